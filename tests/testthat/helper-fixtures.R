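# Shared fixtures: random models, literal-definition landscape oracles and
# a brute-force press-assignment oracle. Oracles implement the definitions
# directly and stay independent of the package's vectorized code paths.

random_mem_model <- function(N, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- stats::runif(N, -scale, scale)
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- stats::runif(N * (N - 1) / 2, -scale, scale)
  J <- J + t(J)
  mem_model(h, J)
}

# energy by direct double sum over the definition
oracle_energy <- function(bits, h, J) {
  N <- length(bits)
  e <- -sum(h * bits)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) e <- e - 0.5 * J[i, j] * bits[i] * bits[j]
    }
  }
  e
}

oracle_bits <- function(code, N) bitwAnd(bitwShiftR(code, 0:(N - 1)), 1L)

oracle_neighbors <- function(code, N) {
  vapply(seq_len(N) - 1L, function(b) bitwXor(code, bitwShiftL(1L, b)),
         integer(1))
}

# literal definition: strictly below all Hamming-1 neighbors
oracle_minima <- function(energies) {
  N <- round(log2(length(energies)))
  keep <- logical(length(energies))
  for (k in seq_along(energies)) {
    nb <- oracle_neighbors(k - 1L, N)
    keep[k] <- all(energies[k] < energies[nb + 1L])
  }
  which(keep) - 1L
}

# literal steepest descent, one pattern at a time
oracle_basin <- function(energies) {
  N <- round(log2(length(energies)))
  vapply(seq_along(energies) - 1L, function(code) {
    k <- code
    repeat {
      nb <- oracle_neighbors(k, N)
      en <- energies[nb + 1L]
      lowest <- nb[en == min(en)]
      best <- min(lowest)                       # tie -> lowest code
      if (energies[best + 1L] < energies[k + 1L]) k <- best else return(k)
    }
  }, integer(1))
}

# Brute-force press assignment: maximize correct responses over the choices
# the algorithm is actually free to make. An in-window press is data: the
# trial whose window holds exactly one press keeps it (even a no-go trial:
# that is how commission errors arise). Free choices are (a) surplus
# in-window presses beyond the fastest, which may serve the neighbor on
# their side of full coherence or be dropped, and (b) out-of-window
# (ambiguous) presses, which may serve either adjacent trial or be dropped.
oracle_max_correct <- function(stream, presses) {
  onsets <- stream$onset
  isi <- attr(stream, "isi")
  n <- length(onsets)
  np <- length(presses)
  window_trial <- vapply(presses, function(p) {
    w <- which(p >= onsets + 0.7 * isi & p <= onsets + 1.4 * isi)
    if (length(w) == 1) w else NA_integer_
  }, integer(1))

  used <- rep(FALSE, n)
  choices <- list()
  for (t in unique(window_trial[!is.na(window_trial)])) {
    ps <- which(!is.na(window_trial) & window_trial == t)
    fastest <- ps[which.min(presses[ps] - onsets[t])]
    used[t] <- TRUE                               # forced: fastest stays
    for (p in setdiff(ps, fastest)) {
      side <- if (presses[p] - onsets[t] >= isi) t + 1L else t - 1L
      opts <- if (side >= 1 && side <= n) c(side, NA) else NA
      choices[[length(choices) + 1L]] <- opts
    }
  }
  for (p in which(is.na(window_trial))) {
    prev <- suppressWarnings(max(which(onsets + 1.4 * isi < presses[p])))
    a <- if (is.finite(prev)) prev else NA_integer_
    b <- if (is.finite(prev)) prev + 1L else 1L
    opts <- c(a, b)
    opts <- opts[!is.na(opts) & opts >= 1 & opts <= n]
    choices[[length(choices) + 1L]] <- c(opts, NA)
  }

  best <- -Inf
  recurse <- function(k, used) {
    if (k > length(choices)) {
      correct <- sum(stream$category == "city" & used) +
        sum(stream$category == "mountain" & !used)
      best <<- max(best, correct)
      return(invisible(NULL))
    }
    for (t in choices[[k]]) {
      if (is.na(t)) {
        recurse(k + 1L, used)                     # drop the press
      } else if (!used[t]) {
        used[t] <- TRUE
        recurse(k + 1L, used)
        used[t] <- FALSE
      }
    }
  }
  recurse(1L, used)
  best
}

random_toy_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1)
  isi <- sample(c(0.8, 1.3), 1)
  category <- ifelse(stats::runif(n) < 0.25, "mountain", "city")
  stream <- trial_stream(category, isi)
  np <- sample(0:8, 1)
  presses <- sort(stats::runif(np, 0, n * isi + 0.6 * isi))
  list(stream = stream, presses = presses)
}

# planted-parameter pools for state-comparison simulations (parameter level,
# no fMRI stage): each participant gets baseline params and a sigma ratio
make_param_pools <- function(n_participants, n_per_state, sigma_ratio = 1,
                             mu_ratio = 1, tau_ratio = 1) {
  lapply(seq_len(n_participants), function(i) {
    mu <- stats::rnorm(1, 0.80, 0.06)
    sigma <- stats::rlnorm(1, log(0.08), 0.25)
    tau <- stats::rlnorm(1, log(0.05), 0.25)
    list(
      "1" = rexgauss(n_per_state, mu, sigma, tau),
      "2" = rexgauss(n_per_state, mu * mu_ratio, sigma * sigma_ratio,
                     tau * tau_ratio)
    )
  })
}
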
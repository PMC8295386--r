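#' Pairwise maximum-entropy (Ising) model over binary network activity
#'
#' Container for the bias vector h and symmetric zero-diagonal coupling
#' matrix J of a pairwise maximum-entropy model over N binary units
#' (brain networks coded active = 1 / inactive = 0). The energy of an
#' activity pattern V is
#' `E(V) = -sum_i h_i sigma_i - 1/2 sum_{i != j} J_ij sigma_i sigma_j`
#' and pattern probabilities follow the Boltzmann law P(V) proportional to
#' exp(-E(V)), so low-energy patterns are the frequent ones.
#'
#' @param h numeric bias vector, length N.
#' @param J numeric N x N symmetric matrix with zero diagonal.
#' @param networks optional character vector of unit names.
#' @return an object of class `mem_model`.
#' @export
mem_model <- function(h, J, networks = NULL) {
  h <- as.numeric(h)
  N <- length(h)
  J <- as.matrix(J)
  if (!all(dim(J) == N)) stop("J must be N x N with N = length(h)")
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-10) stop("J must have zero diagonal")
  if (is.null(networks)) networks <- paste0("net", seq_len(N))
  structure(list(h = h, J = J, N = N, networks = networks, meta = list()),
            class = "mem_model")
}

#' @export
print.mem_model <- function(x, ...) {
  cat(sprintf("pairwise maximum-entropy model over %d units\n", x$N))
  cat("  h:", paste(sprintf("%.3f", x$h), collapse = " "), "\n")
  cat(sprintf("  |J| range: [%.3f, %.3f]\n", min(x$J), max(x$J)))
  if (!is.null(x$meta$iterations)) {
    cat(sprintf("  fitted in %d iterations, final moment mismatch %.2e\n",
                x$meta$iterations, x$meta$mismatch))
  }
  invisible(x)
}

# All 2^N activity patterns as a (2^N x N) 0/1 matrix. Pattern code k
# (0-based) has bit i - 1 as the activity of unit i, so row k + 1 decodes
# code k.
pattern_matrix <- function(N) {
  if (N > 16) stop("exhaustive enumeration supported for N <= 16 only")
  codes <- 0:(2^N - 1)
  vapply(seq_len(N), function(i) bitwAnd(bitwShiftR(codes, i - 1L), 1L),
         integer(2^N))
}

patterns_to_codes <- function(binary) {
  as.integer(binary %*% 2^(seq_len(ncol(binary)) - 1L))
}

#' Energy of activity patterns
#'
#' `E(V) = -sum_i h_i sigma_i - 1/2 sum_{i != j} J_ij sigma_i sigma_j`
#' (each unordered pair counted once after the half and the double sum).
#'
#' @param pattern a 0/1 vector of length N, or a matrix with patterns in
#'   rows.
#' @param model a [mem_model()].
#' @return numeric vector of energies.
#' @export
pattern_energy <- function(pattern, model) {
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1)
  if (ncol(pattern) != model$N) stop("pattern length must equal model N")
  as.numeric(-pattern %*% model$h -
               0.5 * rowSums((pattern %*% model$J) * pattern))
}

# Energies of all 2^N patterns, ordered by pattern code.
all_energies <- function(model) {
  pattern_energy(pattern_matrix(model$N), model)
}

#' Boltzmann pattern probabilities
#'
#' `P(V_k) = exp(-E(V_k)) / sum_l exp(-E(V_l))` over all 2^N patterns,
#' computed with a log-sum-exp guard. Lower energy means higher
#' probability, so energy-landscape minima are the dominant patterns.
#'
#' @param model a [mem_model()] with `model$N <= 16`.
#' @return numeric probability vector of length `2^model$N`, indexed by
#'   pattern code + 1.
#' @export
pattern_probabilities <- function(model) {
  e <- -all_energies(model)
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

#' Empirical activation and pairwise interaction moments
#'
#' First and second moments of a binarized activity matrix:
#' `<sigma_i> = (1/T) sum_t sigma_i^t` and
#' `<sigma_i sigma_j> = (1/T) sum_t sigma_i^t sigma_j^t`.
#'
#' @param binary 0/1 matrix, T volumes x N units.
#' @return list with `m1` (length N) and `m2` (N x N, diagonal =
#'   `m1`).
#' @export
empirical_moments <- function(binary) {
  binary <- as.matrix(binary)
  if (nrow(binary) < 1) stop("need at least one volume")
  list(m1 = colMeans(binary), m2 = crossprod(binary) / nrow(binary))
}

model_moments <- function(P, p) {
  list(m1 = as.numeric(crossprod(P, p)), m2 = crossprod(P, P * p))
}

#' Fit a pairwise maximum-entropy model by gradient ascent
#'
#' Maximum-likelihood fit of (h, J) to binarized activity by moment
#' matching: `h_i <- h_i + eta (<sigma_i>_emp - <sigma_i>_model)` and
#' `J_ij <- J_ij + eta (<sigma_i sigma_j>_emp - <sigma_i sigma_j>_model)`,
#' with model moments from exhaustive enumeration of all 2^N patterns.
#' This is gradient ascent on the exponential-family log-likelihood, so
#' the likelihood is non-decreasing whenever the step is below the
#' stability threshold; the step is backtracked (halved) on any proposed
#' decrease, which makes monotonicity unconditional. Iteration stops when
#' the largest absolute moment mismatch falls below `tol`.
#'
#' Units observed always-on or always-off put the empirical moment on the
#' boundary of the moment polytope, where the MLE diverges; such moments
#' are clamped into `[eps, 1 - eps]` with `eps = 1/(2T)` and a warning.
#'
#' @param binary 0/1 matrix, T volumes x N units (N <= 16).
#' @param step base learning rate eta.
#' @param tol convergence tolerance on the maximum absolute moment
#'   mismatch.
#' @param max_iter iteration cap.
#' @param trace logical; record the per-iteration log-likelihood (per
#'   volume) in `meta$ll_trace`.
#' @param networks optional unit names (defaults to column names).
#' @return a fitted [mem_model()]; `meta` holds `iterations`, `mismatch`,
#'   `converged`, `loglik` and optionally `ll_trace`.
#' @export
fit_mem <- function(binary, step = 0.2, tol = 1e-5, max_iter = 1e5,
                    trace = FALSE, networks = NULL) {
  binary <- as.matrix(binary)
  N <- ncol(binary)
  Tn <- nrow(binary)
  if (N > 16) stop("N <= 16 required (exhaustive enumeration)")
  if (is.null(networks)) networks <- colnames(binary)
  emp <- empirical_moments(binary)
  eps <- 1 / (2 * Tn)
  if (any(emp$m1 <= 0 | emp$m1 >= 1)) {
    warning("unit(s) always on or always off; clamping empirical moments")
    emp$m1 <- pmin(pmax(emp$m1, eps), 1 - eps)
    offd <- !diag(N)
    emp$m2[offd] <- pmin(pmax(emp$m2[offd], eps), 1 - eps)
    diag(emp$m2) <- emp$m1
  }

  P <- pattern_matrix(N)
  h <- numeric(N)
  J <- matrix(0, N, N)
  offdiag <- !diag(N)

  loglik <- function(h, J) {
    e <- as.numeric(P %*% h) + 0.5 * rowSums((P %*% J) * P)
    logZ <- {
      m <- max(e)
      m + base::log(sum(exp(e - m)))
    }
    sum(h * emp$m1) + 0.5 * sum((J * emp$m2)[offdiag]) - logZ
  }

  probs <- function(h, J) {
    e <- as.numeric(P %*% h) + 0.5 * rowSums((P %*% J) * P)
    w <- exp(e - max(e))
    w / sum(w)
  }

  ll <- loglik(h, J)
  ll_trace <- if (trace) numeric(max_iter) else NULL
  iter <- 0L
  mismatch <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    mod <- model_moments(P, probs(h, J))
    g_h <- emp$m1 - mod$m1
    g_J <- emp$m2 - mod$m2
    g_J[!offdiag] <- 0
    mismatch <- max(abs(g_h), abs(g_J))
    if (mismatch < tol) {
      iter <- iter - 1L
      break
    }
    s <- step
    repeat {
      h_new <- h + s * g_h
      J_new <- J + s * g_J
      ll_new <- loglik(h_new, J_new)
      if (ll_new >= ll - 1e-13) break
      if (s < 1e-8) {          # cannot ascend further at numeric precision
        h_new <- h; J_new <- J; ll_new <- ll
        break
      }
      s <- s / 2
    }
    h <- h_new; J <- J_new; ll <- ll_new
    if (trace) ll_trace[iter] <- ll
  }

  out <- mem_model(h, (J + t(J)) / 2, networks = networks)
  out$meta <- list(
    iterations = iter, mismatch = mismatch, converged = mismatch < tol,
    loglik = ll * Tn, tol = tol, step = step,
    ll_trace = if (trace) ll_trace[seq_len(iter)] else NULL
  )
  out
}

#' Model fit quality against empirical pattern frequencies
#'
#' Pearson correlation between the empirical appearance probability of each
#' of the 2^N activity patterns (the time average of the pattern's 1-of-K
#' indicator) and the model's Boltzmann probability.
#'
#' @param binary 0/1 matrix, T x N.
#' @param model a [mem_model()].
#' @return a single correlation, or `NA` with a warning when either vector
#'   has zero variance (e.g. a uniform model scored against uniform data).
#' @export
fit_quality <- function(binary, model) {
  binary <- as.matrix(binary)
  codes <- patterns_to_codes(binary)
  emp <- tabulate(codes + 1L, nbins = 2^model$N) / nrow(binary)
  p <- pattern_probabilities(model)
  if (stats::sd(emp) == 0 || stats::sd(p) == 0) {
    warning("zero variance in appearance probabilities; correlation undefined")
    return(NA_real_)
  }
  stats::cor(emp, p)
}

#' Exact Boltzmann sampling of activity patterns
#'
#' Draws independent patterns from the model's exact Boltzmann distribution
#' by enumerating all 2^N probabilities (feasible for N <= 16). Used for
#' parameter-recovery checks where sampler autocorrelation must not
#' confound the comparison.
#'
#' @param model a [mem_model()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return 0/1 matrix, n x N.
#' @export
sample_patterns <- function(model, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  p <- pattern_probabilities(model)
  codes <- sample.int(length(p), n, replace = TRUE, prob = p) - 1L
  pattern_matrix(model$N)[codes + 1L, , drop = FALSE]
}

#' Residualize, standardize and average ROI series into network activity
#'
#' Per ROI column: ordinary least-squares residual against the supplied
#' confound matrix (an intercept is always included), then per-run
#' standardization to mean 0 / unit variance; network activity is the mean
#' of its member ROI columns. Construction of the confound matrix (motion,
#' task regressors, aCompCor and the like) is the caller's business.
#'
#' @param roi_series numeric matrix, T x R.
#' @param roi_to_network factor/character of length R mapping ROI columns
#'   to network names.
#' @param confounds optional numeric matrix, T x C.
#' @param run optional run label per row; standardization is per run.
#' @return list of class `network_activity`: `values` (T x N matrix),
#'   `networks`, `run`.
#' @export
clean_and_average <- function(roi_series, roi_to_network, confounds = NULL,
                              run = NULL) {
  roi_series <- as.matrix(roi_series)
  Tn <- nrow(roi_series)
  if (length(roi_to_network) != ncol(roi_series)) {
    stop("roi_to_network must map every ROI column")
  }
  if (is.null(run)) run <- rep(1L, Tn)
  X <- cbind(intercept = rep(1, Tn), confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudo-inverse")
    Xr <- X
    beta <- MASS::ginv(crossprod(Xr)) %*% crossprod(Xr, roi_series)
    resid <- roi_series - Xr %*% beta
  } else {
    resid <- as.matrix(stats::lm.fit(X, roi_series)$residuals)
  }
  for (r in unique(run)) {
    idx <- run == r
    mu <- colMeans(resid[idx, , drop = FALSE])
    sd_ <- apply(resid[idx, , drop = FALSE], 2, stats::sd)
    zero <- sd_ < 1e-12
    if (any(zero)) {
      warning("zero-variance ROI column(s) after residualization")
      sd_[zero] <- 1
    }
    resid[idx, ] <- sweep(sweep(resid[idx, , drop = FALSE], 2, mu), 2, sd_, "/")
  }
  nets <- unique(as.character(roi_to_network))
  values <- vapply(nets, function(nm) {
    cols <- which(as.character(roi_to_network) == nm)
    if (length(cols) == 0) stop("empty network: ", nm)
    rowMeans(resid[, cols, drop = FALSE])
  }, numeric(Tn))
  structure(list(values = values, networks = nets, run = run),
            class = "network_activity")
}

#' Binarize network activity at the time mean
#'
#' An entry becomes 1 (active) when it exceeds its column's time-averaged
#' activity computed over the whole series supplied (normally the series
#' concatenated across runs and participants used for the group fit);
#' exact ties become 0.
#'
#' @param activity a `network_activity` object or a plain numeric matrix.
#' @return 0/1 integer matrix of the same dimensions.
#' @export
binarize <- function(activity) {
  values <- if (inherits(activity, "network_activity")) activity$values else as.matrix(activity)
  thr <- colMeans(values)
  out <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  out[sweep(values, 2, thr, ">")] <- 1L
  out
}
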
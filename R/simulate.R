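#' Generate a gradCPT stimulus schedule
#'
#' Random trial stream with the task's design constraints: a fixed
#' mountain (no-go) probability, the default 10% mountain / 90% city mix,
#' scene identities drawn from 10 city and 10 mountain photographs with no
#' identical scene on consecutive trials, and onsets on a constant
#' inter-stimulus-interval grid.
#'
#' @param n_trials number of trials (>= 2).
#' @param isi inter-stimulus interval in seconds.
#' @param p_mountain probability of a mountain trial (default 0.10).
#' @param seed optional integer seed.
#' @param n_scenes scenes per category (default 10).
#' @return a [trial_stream()].
#' @export
gen_trial_stream <- function(n_trials, isi, p_mountain = 0.10, seed = NULL,
                             n_scenes = 10) {
  if (n_trials < 2) stop("'n_trials' must be at least 2")
  if (isi <= 0) stop("'isi' must be positive")
  if (p_mountain < 0 || p_mountain > 1) stop("'p_mountain' must be in [0, 1]")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  category <- ifelse(stats::runif(n_trials) < p_mountain, "mountain", "city")
  scene <- character(n_trials)
  for (k in seq_len(n_trials)) {
    pool <- sprintf("%s_%02d", category[k], seq_len(n_scenes))
    if (k > 1) pool <- setdiff(pool, scene[k - 1])
    scene[k] <- sample(pool, 1)
  }
  trial_stream(category, isi, scene_id = scene)
}

#' Sample binary network dynamics from a pairwise maximum-entropy model
#'
#' Runs a lazy single-flip Metropolis chain (each step holds with
#' probability 1/2, removing the parity periodicity of the pure chain)
#' whose stationary law is the model's Boltzmann distribution, recording
#' one pattern every `dwell_control` steps. Small `dwell_control` yields temporally persistent, slowly
#' mixing state dynamics (BOLD-like); large values approach independent
#' draws. A continuous companion signal is emitted as +/- `amplitude`
#' (active/inactive) plus unit-variance Gaussian observation noise, so
#' that mean-thresholding recovers the binary truth with high probability.
#'
#' The chain is initialized from the exact Boltzmann distribution, so
#' every recorded volume is marginally stationary.
#'
#' @param model a [mem_model()] (N <= 16).
#' @param volumes number of volumes to record (>= 1).
#' @param dwell_control Metropolis steps between recorded volumes (>= 1).
#' @param seed optional integer seed.
#' @param amplitude offset of the continuous signal (default 1).
#' @return list with `binary` (volumes x N) and `values` (volumes x N
#'   noisy continuous signal).
#' @export
gen_network_series <- function(model, volumes, dwell_control = 10,
                               seed = NULL, amplitude = 1) {
  if (volumes < 1) stop("'volumes' must be at least 1")
  if (dwell_control < 1) stop("'dwell_control' must be at least 1")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  N <- model$N
  h <- model$h
  J <- model$J
  s <- as.integer(sample_patterns(model, 1))
  nstep <- volumes * dwell_control
  units <- sample.int(N, nstep, replace = TRUE)
  us <- stats::runif(nstep)
  binary <- matrix(0L, volumes, N)
  step <- 0L
  for (v in seq_len(volumes)) {
    for (d in seq_len(dwell_control)) {
      step <- step + 1L
      u <- us[step]
      if (u < 0.5) next                      # lazy hold: kills periodicity
      u <- (u - 0.5) * 2
      i <- units[step]
      dE <- -(h[i] + sum(J[, i] * s)) * (1 - 2 * s[i])
      if (dE <= 0 || u < exp(-dE)) s[i] <- 1L - s[i]
    }
    binary[v, ] <- s
  }
  colnames(binary) <- model$networks
  values <- (2 * binary - 1) * amplitude +
    matrix(stats::rnorm(volumes * N), volumes, N)
  colnames(values) <- model$networks
  list(binary = binary, values = values)
}

#' Planted two-state Ising model
#'
#' A Hopfield-style one-pattern construction over the eight canonical
#' networks: spin couplings `K = coupling / N * xi xi'` with `xi = +1` on
#' FPN_A, DMN and Limbic and `-1` elsewhere, mapped from the +/-1 spin
#' convention to the 0/1 activity convention. Its two energy minima are
#' the State1 template (FPN_A, DMN, Limbic active) and its complement
#' (the State2 template), giving a ground-truth two-state landscape for
#' end-to-end simulations.
#'
#' @param coupling Hopfield coupling strength (controls basin depth and
#'   dwell times; the default gives two clear minima with comparable basin
#'   mass).
#' @param networks unit names (default [gradstate_networks]).
#' @param state1_active names of the units active in State1.
#' @return a [mem_model()]; attribute `templates` holds the two planted
#'   minimum pattern codes.
#' @export
planted_two_state_model <- function(coupling = 1.6,
                                    networks = gradstate_networks,
                                    state1_active = c("FPN_A", "DMN", "Limbic")) {
  N <- length(networks)
  xi <- ifelse(networks %in% state1_active, 1, -1)
  K <- coupling / N * (xi %o% xi)
  diag(K) <- 0
  # spin -> 0/1 convention: x = 2 sigma - 1
  J <- 4 * K
  h <- -2 * colSums(K)
  model <- mem_model(h, J, networks = networks)
  attr(model, "templates") <- c(
    state1 = sum(2^(which(xi == 1) - 1)),
    state2 = sum(2^(which(xi == -1) - 1))
  )
  model
}

#' Simulate gradCPT button presses conditioned on a brain-state series
#'
#' For each city (go) trial the participant presses with probability
#' `1 - omission_rate(state)` at `onset + RT`, the RT drawn from the
#' state's exGaussian; mountain (no-go) trials draw a commission press
#' with probability `commission_rate(state)`. With probability
#' `ambiguous_press_rate` a press is displaced into the ambiguous window
#' between consecutive response windows: by default onto the slow side
#' (after 40% coherence of the following scene), the dominant source of
#' ambiguity in this task, with the displaced RT drawn from the
#' exponential tail of the state's own RT process truncated to the gap
#' (deviant responses are slow realizations, not uniform noise);
#' `anticipation_fraction` of displaced presses instead land early
#' (before 70% coherence of the current scene). With
#' probability `multipress_rate` a rapid second tap follows 50-150 ms
#' after the first press. The generating state of a trial is the label of
#' the volume covering the trial onset, advanced by the same integer
#' hemodynamic-lag shift (`round(lag / tr)`, halves down) that the
#' analysis pipeline later removes, so round-trip tests line up exactly.
#'
#' @param stream a [trial_stream()].
#' @param states integer/character vector of per-volume state labels
#'   (unshifted acquisition order).
#' @param state_params named list keyed by state label; each element a
#'   list with `mu`, `sigma`, `tau`, `omission_rate`, `commission_rate`.
#' @param tr repetition time in seconds.
#' @param lag hemodynamic lag in seconds (default 5).
#' @param ambiguous_press_rate,multipress_rate nuisance-press
#'   probabilities (defaults 0).
#' @param anticipation_fraction fraction of displaced presses landing on
#'   the early (anticipatory) side; default 0, as anticipations are not
#'   modelled as a class of their own.
#' @param seed optional integer seed.
#' @return list with `presses` (sorted timestamps) and `truth`
#'   (data.frame: trial, onset, category, state, responded, true_rt,
#'   displaced, extra_press).
#' @export
gen_behavior <- function(stream, states, state_params, tr, lag = 5,
                         ambiguous_press_rate = 0, multipress_rate = 0,
                         anticipation_fraction = 0, seed = NULL) {
  stopifnot(inherits(stream, "trial_stream"))
  if (length(states) == 0) stop("empty state series")
  isi <- attr(stream, "isi")
  n <- nrow(stream)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  # the same integer lag shift the analysis applies (halves round down), so
  # generated labels and lag-shifted pipeline labels coincide exactly
  shift <- as.integer(ceiling(lag / tr - 0.5))
  vol <- floor(stream$onset / tr) + 1L + shift
  if (max(vol) > length(states)) {
    stop("state series does not cover the run duration (after lag)")
  }
  lab <- as.character(states[vol])
  if (!all(lab %in% names(state_params))) {
    stop("state label(s) missing from state_params: ",
         paste(setdiff(unique(lab), names(state_params)), collapse = ", "))
  }

  presses <- numeric(0)
  truth <- data.frame(
    trial = seq_len(n), onset = stream$onset, category = stream$category,
    state = lab, responded = FALSE, true_rt = NA_real_,
    displaced = FALSE, extra_press = FALSE, stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    sp <- state_params[[lab[k]]]
    responds <- if (stream$category[k] == "city") {
      stats::runif(1) >= (sp$omission_rate %||% 0)
    } else {
      stats::runif(1) < (sp$commission_rate %||% 0)
    }
    if (!responds) next
    rt <- rexgauss(1, sp$mu, sp$sigma, sp$tau)
    if (ambiguous_press_rate > 0 && stats::runif(1) < ambiguous_press_rate) {
      rt <- if (stats::runif(1) < anticipation_fraction) {
        stats::runif(1, 0.4 * isi, 0.7 * isi)     # before 70% coherence
      } else {
        # a deviant slow response: the exGaussian tail beyond the response
        # window is exponential(tau) by the memoryless tail property;
        # truncate it to the ambiguous gap (before 70% of the next scene)
        u <- stats::runif(1)
        1.4 * isi - sp$tau * base::log(1 - u * (1 - exp(-0.3 * isi / sp$tau)))
      }
      truth$displaced[k] <- TRUE
    }
    truth$responded[k] <- TRUE
    truth$true_rt[k] <- rt
    presses <- c(presses, stream$onset[k] + rt)
    if (multipress_rate > 0 && stats::runif(1) < multipress_rate) {
      presses <- c(presses, stream$onset[k] + rt + stats::runif(1, 0.05, 0.15))
      truth$extra_press[k] <- TRUE
    }
  }
  list(presses = sort(presses), truth = truth)
}

#' Generate a participant population with planted parameter-error links
#'
#' Draws per-participant exGaussian parameters (mu Gaussian; sigma and tau
#' lognormal so they stay positive, with moments matched to the requested
#' mean/sd) and error rates that are monotone functions of latent
#' parameter scores plus noise, so that planted Spearman correlations
#' between a parameter and an error rate are recoverable from the sample.
#' Planted rank correlations are converted to latent Pearson correlations
#' through the Gaussian-copula identity `rho = 2 sin(pi rho_s / 6)`.
#'
#' @param n_participants number of participants.
#' @param means,sds named numeric vectors over `mu`, `sigma`, `tau`
#'   (defaults match a positively skewed gradCPT population: 0.80 / 0.08 /
#'   0.05 with spreads 0.06 / 0.03 / 0.02).
#' @param rho_omission,rho_commission named numeric vectors of planted
#'   Spearman correlations between parameters and the error scores (the
#'   squared latent loadings must sum to at most 1).
#' @param base_omission,base_commission baseline error rates on the
#'   logistic scale.
#' @param error_spread logistic-scale spread of the error scores.
#' @param seed optional integer seed.
#' @return data.frame: participant, mu, sigma, tau, omission_rate,
#'   commission_rate.
#' @export
gen_population <- function(n_participants,
                           means = c(mu = 0.80, sigma = 0.08, tau = 0.05),
                           sds = c(mu = 0.06, sigma = 0.03, tau = 0.02),
                           rho_omission = c(sigma = 0.5),
                           rho_commission = NULL,
                           base_omission = 0.10, base_commission = 0.25,
                           error_spread = 1, seed = NULL) {
  if (any(sds < 0)) stop("'sds' must be non-negative")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  pars <- c("mu", "sigma", "tau")
  z <- matrix(stats::rnorm(n_participants * 3), n_participants, 3,
              dimnames = list(NULL, pars))
  lognorm <- function(zcol, m, s) {
    if (s == 0) return(rep(m, length(zcol)))
    sdlog <- sqrt(base::log(1 + (s / m)^2))
    exp(base::log(m) - sdlog^2 / 2 + sdlog * zcol)
  }
  mu <- means["mu"] + sds["mu"] * z[, "mu"]
  sigma <- lognorm(z[, "sigma"], means["sigma"], sds["sigma"])
  tau <- lognorm(z[, "tau"], means["tau"], sds["tau"])

  error_score <- function(rho_s) {
    load <- rep(0, 3); names(load) <- pars
    if (length(rho_s)) {
      if (!all(names(rho_s) %in% pars)) stop("rho names must be mu/sigma/tau")
      load[names(rho_s)] <- 2 * sin(pi * rho_s / 6)
    }
    if (sum(load^2) > 1) stop("planted correlations too strong (sum of squared loadings > 1)")
    as.numeric(z %*% load) +
      sqrt(1 - sum(load^2)) * stats::rnorm(n_participants)
  }
  om <- stats::plogis(stats::qlogis(base_omission) + error_spread * error_score(rho_omission))
  co <- stats::plogis(stats::qlogis(base_commission) + error_spread * error_score(rho_commission))

  data.frame(
    participant = seq_len(n_participants),
    mu = as.numeric(mu), sigma = as.numeric(sigma), tau = as.numeric(tau),
    omission_rate = om, commission_rate = co
  )
}
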
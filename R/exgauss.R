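#' The exGaussian distribution
#'
#' Density and random generation for the exGaussian (exponentially modified
#' Gaussian) distribution: the convolution of a Normal(mu, sigma^2) and an
#' Exponential with mean tau. In reaction-time work mu captures central
#' tendency (the "strategy factor"), sigma the spread of the Gaussian core
#' (the "variance factor") and tau the exponential right tail (the
#' "long-tail factor"). The implied mean is `mu + tau` and the implied
#' variance `sigma^2 + tau^2`.
#'
#' The density is evaluated in the log domain,
#' `log f(x) = -log(tau) + sigma^2/(2 tau^2) - (x - mu)/tau +
#'  log Phi((x - mu)/sigma - sigma/tau)`,
#' with the Gaussian CDF taken on the log scale; the naive closed form
#' overflows for small tau.
#'
#' @param x numeric vector of quantiles (seconds).
#' @param n number of draws.
#' @param mu Gaussian component mean (seconds).
#' @param sigma Gaussian component standard deviation (seconds, > 0).
#' @param tau exponential component mean (seconds, > 0).
#' @param log logical; return log-density?
#' @return `dexgauss` a numeric vector of (log-)densities; `rexgauss` a
#'   numeric vector of draws.
#' @examples
#' dexgauss(0.85, mu = 0.80, sigma = 0.08, tau = 0.05)
#' summary(rexgauss(1000, 0.80, 0.08, 0.05))
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  if (any(sigma <= 0) || any(tau <= 0)) {
    stop("'sigma' and 'tau' must be strictly positive")
  }
  z <- (x - mu) / sigma
  lf <- -base::log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  if (sigma <= 0 || tau <= 0) stop("'sigma' and 'tau' must be strictly positive")
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Theoretical exGaussian moments
#'
#' Mean and variance implied by an exGaussian parameter triple:
#' mean = mu + tau, variance = sigma^2 + tau^2.
#'
#' @param mu,sigma,tau exGaussian parameters; alternatively pass an
#'   `exgauss_fit` object as `mu`.
#' @return named numeric vector with elements `mean` and `variance`.
#' @examples
#' exgauss_moments(0.80, 0.08, 0.05)
#' @export
exgauss_moments <- function(mu, sigma, tau) {
  if (inherits(mu, "exgauss_fit")) {
    fit <- mu
    mu <- fit$mu; sigma <- fit$sigma; tau <- fit$tau
  }
  if (sigma <= 0 || tau <= 0) stop("'sigma' and 'tau' must be strictly positive")
  c(mean = mu + tau, variance = sigma^2 + tau^2)
}

#' Bias-corrected sample skewness
#'
#' Adjusted Fisher-Pearson standardized third moment,
#' `g1 * sqrt(n (n - 1)) / (n - 2)`; the estimator whose sign decides
#' whether a reaction-time sample is fitted directly or on the flipped scale.
#'
#' @param x numeric vector, length >= 3.
#' @return a single numeric value.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations for skewness")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NaN)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

insufficient_data <- function(msg, n) {
  stop(structure(
    class = c("gradstate_insufficient_data", "error", "condition"),
    list(message = msg, call = sys.call(-1), n = n)
  ))
}

#' Maximum-likelihood exGaussian fit
#'
#' Fits (mu, sigma, tau) to a vector of correct-commission reaction times by
#' maximum likelihood, optimizing over (mu, log sigma, log tau) with
#' moment-matched starting values (tau0 = sd * (skew/2)^(1/3),
#' sigma0^2 = max(var - tau0^2, eps), mu0 = mean - tau0). A Gaussian
#' comparator (mu_normal = sample mean, sigma_normal = MLE standard
#' deviation) and its log-likelihood are always recorded.
#'
#' @param rts numeric vector of reaction times (seconds).
#' @param min_trials minimum number of observations; fewer signals a classed
#'   `gradstate_insufficient_data` error so callers can exclude the unit
#'   rather than receive a silent degenerate fit.
#' @return an object of class `exgauss_fit`: a list with elements `mu`,
#'   `sigma`, `tau`, `flipped`, `loglik`, `loglik_gauss`, `mu_normal`,
#'   `sigma_normal`, `skewness`, `n`, `convergence`.
#' @examples
#' set.seed(1)
#' fit_exgauss(rexgauss(2000, 0.80, 0.08, 0.05))
#' @export
fit_exgauss <- function(rts, min_trials = 10) {
  rts <- as.numeric(rts)
  if (anyNA(rts)) rts <- rts[!is.na(rts)]
  n <- length(rts)
  if (n < min_trials) {
    insufficient_data(sprintf("only %d RTs; need at least %d", n, min_trials), n)
  }
  if (stats::sd(rts) == 0) {
    insufficient_data("zero-variance RT sample cannot identify sigma and tau", n)
  }

  m <- mean(rts)
  v <- stats::var(rts)
  sk <- sample_skewness(rts)
  tau0 <- sqrt(v) * (max(sk, 0.05) / 2)^(1 / 3)
  sigma0 <- sqrt(max(v - tau0^2, 0.01 * v))
  mu0 <- m - tau0

  nll <- function(par) {
    val <- -sum(dexgauss(rts, par[1], exp(par[2]), exp(par[3]), log = TRUE))
    if (!is.finite(val)) .Machine$double.xmax / 2 else val
  }
  opt <- stats::optim(
    c(mu0, base::log(sigma0), base::log(tau0)), nll,
    method = "L-BFGS-B",
    lower = c(m - 10 * sqrt(v) - 1, base::log(sqrt(v) * 1e-4), base::log(sqrt(v) * 1e-4)),
    upper = c(m + 10 * sqrt(v) + 1, base::log(sqrt(v) * 10 + 1), base::log(sqrt(v) * 10 + 1)),
    control = list(factr = 1e5, maxit = 500)
  )

  sigma_n <- sqrt(mean((rts - m)^2))      # MLE (1/n) Gaussian comparator
  ll_gauss <- sum(stats::dnorm(rts, m, sigma_n, log = TRUE))

  structure(list(
    mu = opt$par[1],
    sigma = exp(opt$par[2]),
    tau = exp(opt$par[3]),
    flipped = FALSE,
    loglik = -opt$value,
    loglik_gauss = ll_gauss,
    mu_normal = m,
    sigma_normal = sigma_n,
    skewness = sk,
    n = n,
    convergence = opt$convergence
  ), class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf(
    "exGaussian fit (n = %d%s)\n  mu = %.4f  sigma = %.4f  tau = %.4f\n  logLik = %.2f (Gaussian %.2f)  skewness = %.2f\n",
    x$n, if (x$flipped) ", fitted on flipped RTs" else "",
    x$mu, x$sigma, x$tau, x$loglik, x$loglik_gauss, x$skewness
  ))
  invisible(x)
}

#' exGaussian fit with a negative-skew policy
#'
#' Reaction-time samples with negative sample skewness are incompatible with
#' the exGaussian's positive tail. Under `policy = "flip"` such samples are
#' fitted on the sign-reversed scale and the location is mapped back
#' (mu := -mu_fit), keeping sigma and tau as fitted, with `flipped = TRUE`.
#' Under `policy = "exclude"` the unit is marked excluded (the behavior used
#' when combining parameters across brain states, where an unambiguous slow
#' tail is required).
#'
#' @param rts numeric vector of reaction times.
#' @param policy `"flip"` or `"exclude"`.
#' @param min_trials passed to [fit_exgauss()].
#' @return an `exgauss_fit`, or (only under `policy = "exclude"` with
#'   negative skew) an object of class `exgauss_exclusion` carrying the
#'   reason and the measured skewness.
#' @export
fit_with_skew_policy <- function(rts, policy = c("flip", "exclude"),
                                 min_trials = 10) {
  policy <- match.arg(policy)
  rts <- as.numeric(rts[!is.na(rts)])
  if (length(rts) < min_trials) {
    insufficient_data(
      sprintf("only %d RTs; need at least %d", length(rts), min_trials),
      length(rts)
    )
  }
  sk <- sample_skewness(rts)
  if (is.nan(sk) || sk >= 0) {
    return(fit_exgauss(rts, min_trials = min_trials))
  }
  if (policy == "exclude") {
    return(structure(
      list(excluded = TRUE, reason = "negative_skew", skewness = sk,
           n = length(rts)),
      class = "exgauss_exclusion"
    ))
  }
  fit <- fit_exgauss(-rts, min_trials = min_trials)
  fit$mu <- -fit$mu
  fit$flipped <- TRUE
  fit$skewness <- sk
  fit$mu_normal <- mean(rts)
  fit
}

#' @export
print.exgauss_exclusion <- function(x, ...) {
  cat(sprintf("excluded unit (n = %d): %s (skewness %.2f)\n",
              x$n, x$reason, x$skewness))
  invisible(x)
}

#' Simulation-based R-squared goodness of fit
#'
#' Compares the empirical RT histogram with the histogram of a large sample
#' simulated from the fitted distribution. Bin width follows the
#' Freedman-Diaconis rule computed on the empirical sample; both samples are
#' binned on the same grid (extended to cover both ranges) and compared as
#' densities: r2 = 1 - SS_res / SS_tot across bins.
#'
#' @param rts empirical reaction times.
#' @param fit an `exgauss_fit` (flipped fits are simulated on the mirrored
#'   scale and mapped back, so the comparison happens on the RT scale).
#' @param distribution `"exgauss"` or `"gauss"` (the Gaussian comparator
#'   stored in the fit).
#' @param sim_n simulated sample size; default `max(10 * length(rts), 10000)`.
#' @param seed optional integer seed for the simulation draw.
#' @return a single numeric r-squared (<= 1).
#' @export
goodness_r2 <- function(rts, fit, distribution = c("exgauss", "gauss"),
                        sim_n = NULL, seed = NULL) {
  distribution <- match.arg(distribution)
  rts <- as.numeric(rts[!is.na(rts)])
  if (length(rts) == 0) stop("empty RT vector")
  if (is.null(sim_n)) sim_n <- max(10L * length(rts), 10000L)
  if (sim_n < 10L * length(rts)) stop("sim_n must be at least 10x the data size")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  sim <- switch(distribution,
    exgauss = if (isTRUE(fit$flipped)) {
      -rexgauss(sim_n, -fit$mu, fit$sigma, fit$tau)
    } else {
      rexgauss(sim_n, fit$mu, fit$sigma, fit$tau)
    },
    gauss = stats::rnorm(sim_n, fit$mu_normal, fit$sigma_normal)
  )
  h <- 2 * stats::IQR(rts) / length(rts)^(1 / 3)
  if (h <= 0) h <- diff(range(rts)) / 30
  if (h <= 0) stop("degenerate RT sample: zero spread")
  lo <- min(rts, sim)
  hi <- max(rts, sim)
  breaks <- seq(lo - h, hi + h, by = h)
  d_emp <- graphics::hist(rts, breaks = breaks, plot = FALSE)$density
  d_sim <- graphics::hist(sim, breaks = breaks, plot = FALSE)$density
  1 - sum((d_emp - d_sim)^2) / sum((d_emp - mean(d_emp))^2)
}

#' Split-half reliability with the Spearman-Brown correction
#'
#' Correlates a per-participant parameter estimated on the first half of a
#' session with the same parameter estimated on the second half, and applies
#' the Spearman-Brown step-up formula, reliability = 2 r / (1 + r).
#'
#' @param first,second paired numeric vectors (one value per participant).
#' @param method correlation method passed to [stats::cor()].
#' @return list with elements `r` (half-half correlation) and `reliability`.
#' @export
split_half_reliability <- function(first, second, method = "pearson") {
  if (length(first) != length(second)) stop("halves must be paired")
  keep <- stats::complete.cases(first, second)
  first <- first[keep]; second <- second[keep]
  if (length(first) < 3) stop("need at least 3 paired observations")
  if (stats::sd(first) == 0 || stats::sd(second) == 0) {
    stop(structure(
      class = c("gradstate_undefined_statistic", "error", "condition"),
      list(message = "zero variance in one half; reliability undefined",
           call = sys.call())
    ))
  }
  r <- stats::cor(first, second, method = method)
  list(r = r, reliability = 2 * r / (1 + r))
}
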
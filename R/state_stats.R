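#' Pool correct-commission reaction times by brain state
#'
#' Each correct-commission trial is assigned the brain-state label of the
#' volume whose acquisition interval `[v * tr, (v + 1) * tr)` contains the
#' trial onset, using the lag-shifted state series; trials whose onset
#' falls beyond the labelled span are dropped and counted.
#'
#' @param rts an `rt_series` from [assign_presses()].
#' @param states a [state_series()] (or a plain vector of per-volume
#'   labels, in which case `tr` must be given).
#' @param tr repetition time; taken from `states` when it is a
#'   `state_series`.
#' @return list of class `state_rt_pools`: `pools` (named list of RT
#'   vectors keyed by state label), `n_dropped`.
#' @export
pool_rts <- function(rts, states, tr = NULL) {
  if (inherits(states, "state_series")) {
    tr <- states$tr
    labels <- states$state
  } else {
    labels <- states
    if (is.null(tr)) stop("'tr' required when states is a plain vector")
  }
  cc <- rts$classification == "correct_commission"
  onsets <- rts$onset[cc]
  rtv <- rts$rt[cc]
  vol <- floor(onsets / tr) + 1L
  keep <- vol >= 1L & vol <= length(labels)
  if (!any(keep) && length(onsets) > 0) stop("state series does not overlap any trial")
  lab <- as.character(labels[vol[keep]])
  pools <- split(rtv[keep], lab)
  structure(list(pools = pools, n_dropped = sum(!keep)),
            class = "state_rt_pools")
}

#' Hedges' g with pooled standardizer
#'
#' Small-sample-corrected standardized mean difference,
#' `g = J(df) * (mean1 - mean2) / s_pooled`, with the pooled SD from the
#' two condition SDs and `J(df) = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`.
#'
#' @param x1,x2 numeric vectors (paired or not; the standardizer is the
#'   pooled condition SD, not the SD of differences).
#' @return a single numeric effect size.
#' @export
hedges_g <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / df)
  corr <- 1 - 3 / (4 * df - 1)
  corr * (mean(x1) - mean(x2)) / sp
}

#' Compare exGaussian parameters between two brain states
#'
#' Fits an exGaussian per state per participant (skew policy: exclude, so
#' the long-tail factor is unambiguously a slow tail) and runs, for each
#' parameter, a two-tailed paired t-test across participants plus Hedges'
#' g. A participant enters only when both state pools pass `min_trials`
#' correct commissions and neither is negatively skewed; exclusions are
#' joint across all three parameters, keeping the paired design balanced.
#'
#' @param pools_by_participant list over participants; each element a
#'   `state_rt_pools` or a plain named list of RT vectors.
#' @param state_a,state_b the two state labels to compare.
#' @param min_trials minimum correct commissions per state pool.
#' @return object of class `state_comparison`: `table` (one row per
#'   parameter with state means, t, df, p, Hedges' g), `params` (included
#'   participants x parameter x state array), `n_included`, `exclusions`
#'   (data.frame participant/reason).
#' @export
compare_states <- function(pools_by_participant, state_a, state_b,
                           min_trials = 10) {
  state_a <- as.character(state_a)
  state_b <- as.character(state_b)
  n_part <- length(pools_by_participant)
  fits <- list()
  excl <- data.frame(participant = integer(0), reason = character(0))
  for (i in seq_len(n_part)) {
    pl <- pools_by_participant[[i]]
    if (inherits(pl, "state_rt_pools")) pl <- pl$pools
    ra <- pl[[state_a]]; rb <- pl[[state_b]]
    if (is.null(ra) || is.null(rb) ||
        length(ra) < min_trials || length(rb) < min_trials) {
      excl <- rbind(excl, data.frame(participant = i, reason = "insufficient_trials"))
      next
    }
    fa <- tryCatch(fit_with_skew_policy(ra, "exclude", min_trials),
                   gradstate_insufficient_data = function(e) NULL)
    fb <- tryCatch(fit_with_skew_policy(rb, "exclude", min_trials),
                   gradstate_insufficient_data = function(e) NULL)
    if (is.null(fa) || is.null(fb)) {
      excl <- rbind(excl, data.frame(participant = i, reason = "degenerate_fit"))
      next
    }
    if (inherits(fa, "exgauss_exclusion") || inherits(fb, "exgauss_exclusion")) {
      excl <- rbind(excl, data.frame(participant = i, reason = "negative_skew"))
      next
    }
    fits[[length(fits) + 1L]] <- list(participant = i, a = fa, b = fb)
  }
  n_inc <- length(fits)
  if (n_inc < 3) {
    stop(structure(
      class = c("gradstate_no_result", "error", "condition"),
      list(message = sprintf(
        "only %d participants usable (need >= 3); %d excluded",
        n_inc, nrow(excl)), call = sys.call())
    ))
  }
  pars <- c("mu", "sigma", "tau")
  arr <- array(NA_real_, dim = c(n_inc, 3, 2),
               dimnames = list(NULL, pars, c(state_a, state_b)))
  for (j in seq_len(n_inc)) {
    for (p in pars) {
      arr[j, p, 1] <- fits[[j]]$a[[p]]
      arr[j, p, 2] <- fits[[j]]$b[[p]]
    }
  }
  tab <- do.call(rbind, lapply(pars, function(p) {
    xa <- arr[, p, 1]; xb <- arr[, p, 2]
    d <- xa - xb
    if (stats::sd(d) == 0) {
      # identical paired values: no evidence of a difference
      tstat <- 0; dfree <- n_inc - 1; pval <- 1
      g <- if (stats::sd(c(xa, xb)) == 0) 0 else hedges_g(xa, xb)
    } else {
      tt <- stats::t.test(xa, xb, paired = TRUE)
      tstat <- unname(tt$statistic); dfree <- unname(tt$parameter)
      pval <- tt$p.value; g <- hedges_g(xa, xb)
    }
    data.frame(
      parameter = p, mean_a = mean(xa), mean_b = mean(xb),
      t = tstat, df = dfree, p_value = pval, hedges_g = g,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    table = tab, params = arr, n_included = n_inc,
    included = vapply(fits, `[[`, integer(1), "participant"),
    exclusions = excl, states = c(state_a, state_b)
  ), class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("exGaussian parameters by brain state (%s vs %s): %d included, %d excluded\n",
              x$states[1], x$states[2], x$n_included, nrow(x$exclusions)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman correlation between a parameter and an outcome
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' comes from the t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
correlate_params <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(structure(
      class = c("gradstate_undefined_statistic", "error", "condition"),
      list(message = "constant vector; rank correlation undefined",
           call = sys.call())
    ))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Multiple regression of an error count on exGaussian parameters
#'
#' Ordinary least squares of the outcome on (mu, sigma, tau) plus an
#' intercept, reporting raw coefficients with t and p, the overall R^2
#' and F, and standardized coefficients (all variables z-scored).
#'
#' @param params numeric matrix/data.frame with columns mu, sigma, tau.
#' @param errors numeric outcome per participant (n > 4).
#' @return list with `coefficients` (data.frame: term, estimate,
#'   std_estimate, t, p), `r_squared`, `f_statistic`, `df`.
#' @export
regress_errors <- function(params, errors) {
  params <- as.data.frame(params)[, c("mu", "sigma", "tau")]
  n <- nrow(params)
  if (n <= 4) stop("need more than 4 observations")
  X <- cbind(intercept = 1, as.matrix(params))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear predictors; using pseudo-inverse")
    XtXi <- MASS::ginv(crossprod(X))
  } else {
    XtXi <- solve(crossprod(X))
  }
  beta <- as.numeric(XtXi %*% crossprod(X, errors))
  res <- errors - X %*% beta
  df_res <- n - qx$rank
  s2 <- sum(res^2) / df_res
  se <- sqrt(diag(XtXi) * s2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  ss_tot <- sum((errors - mean(errors))^2)
  r2 <- 1 - sum(res^2) / ss_tot
  f <- (r2 / (qx$rank - 1)) / ((1 - r2) / df_res)
  sd_y <- stats::sd(errors)
  std <- c(NA, beta[-1] * apply(params, 2, stats::sd) / sd_y)
  list(
    coefficients = data.frame(
      term = colnames(X), estimate = beta, std_estimate = std,
      t = tval, p = pval, stringsAsFactors = FALSE
    ),
    r_squared = r2,
    f_statistic = f,
    df = c(qx$rank - 1, df_res)
  )
}

#' Correlation between the variance factor and mind-wandering
#'
#' Spearman correlation between per-participant sigma (or any parameter)
#' and the participant's mean thought-probe rating (0 = only task,
#' 100 = only else).
#'
#' @param sigma numeric vector, one value per participant.
#' @param probes numeric vector of per-participant probe means, or a list
#'   of per-probe responses which are averaged; all values must lie in
#'   [0, 100].
#' @return as [correlate_params()].
#' @export
mind_wandering_correlation <- function(sigma, probes) {
  if (is.list(probes)) probes <- vapply(probes, mean, numeric(1))
  if (any(probes < 0 | probes > 100, na.rm = TRUE)) {
    stop("probe scores must lie in [0, 100]")
  }
  correlate_params(sigma, probes)
}
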
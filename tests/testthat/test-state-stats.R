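test_that("RT pooling follows the lag-shifted volume labels", {
  st <- trial_stream(rep("city", 40), isi = 0.8)
  out <- assign_presses(st, st$onset + 0.8)

  # single-state series: everything lands in one pool
  single <- pool_rts(out, rep(5L, 20), tr = 2)
  expect_length(single$pools, 1L)
  expect_length(single$pools[["5"]], 40L)

  # one trial per volume, alternating states: pools of equal size
  st1 <- trial_stream(rep("city", 40), isi = 2)
  out1 <- assign_presses(st1, st1$onset + 2)
  alt <- pool_rts(out1, rep(c(1L, 2L), 20), tr = 2)
  expect_lte(abs(length(alt$pools[["1"]]) - length(alt$pools[["2"]])), 1L)

  # trials beyond the labelled span are dropped and counted
  short <- pool_rts(out, rep(1L, 10), tr = 2)
  expect_equal(length(short$pools[["1"]]) + short$n_dropped, 40L)
  expect_gt(short$n_dropped, 0L)
})

test_that("generator states round-trip through pooling when observation noise is off", {
  m <- planted_two_state_model()
  ls <- energy_landscape(m)
  stream <- gen_trial_stream(300, 0.8, 0, seed = 60)
  net <- gen_network_series(m, 125, 10, seed = 61)
  true_states <- ls$basin[gradstate:::patterns_to_codes(net$binary) + 1L]
  sp <- list()
  for (code in ls$minima) {
    sp[[as.character(code)]] <- list(mu = 0.8, sigma = 0.05, tau = 0.03,
                                     omission_rate = 0, commission_rate = 0)
  }
  beh <- gen_behavior(stream, true_states, sp, tr = 2, lag = 5, seed = 62)
  rts <- assign_presses(stream, beh$presses)
  # noise-free path: pool on the true binary series and true landscape
  ss <- state_series(net$binary, ls, tr = 2, lag = 5)
  pools <- pool_rts(rts, ss)
  # every pooled RT carries the state the generator drew it under
  vol <- floor(beh$truth$onset / 2) + 1L
  covered <- vol <= length(ss$state)
  for (code in names(pools$pools)) {
    expected <- beh$truth$true_rt[beh$truth$state == code &
                                    beh$truth$responded & covered]
    expect_equal(pools$pools[[code]], expected)
  }
  expect_equal(sum(lengths(pools$pools)) + pools$n_dropped,
               sum(beh$truth$responded))
})

test_that("paired comparison reproduces hand-computed t and handles identical pools", {
  # engineered parameter arrays through pools: use direct fits on planted
  # samples is slow; instead drive compare_states with deterministic pools
  set.seed(63)
  base <- rexgauss(400, 0.8, 0.08, 0.05)
  pools <- lapply(1:5, function(i) {
    x <- rexgauss(400, 0.8, 0.08, 0.05)
    list("1" = x, "2" = x)   # identical in both states
  })
  cmp <- compare_states(pools, "1", "2")
  expect_true(all(cmp$table$t == 0))
  expect_true(all(cmp$table$hedges_g == 0))
  expect_true(all(cmp$table$p_value == 1))
  expect_equal(cmp$table$df, rep(4, 3))

  # hand-computed paired t on the differences (1,2,3) vs (2,3,5)
  d <- c(1, 2, 3) - c(2, 3, 5)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  tt <- t.test(c(1, 2, 3), c(2, 3, 5), paired = TRUE)
  expect_equal(unname(tt$statistic), t_hand)
  expect_equal(abs(t_hand), 4)

  # exclusion bookkeeping: counts always partition the sample
  pools2 <- c(pools, list(list("1" = base[1:5], "2" = base[1:5])))
  cmp2 <- compare_states(pools2, "1", "2")
  expect_equal(cmp2$n_included + nrow(cmp2$exclusions), length(pools2))
  expect_true("insufficient_trials" %in% cmp2$exclusions$reason)

  expect_error(compare_states(pools[1:2], "1", "2"),
               class = "gradstate_no_result")
})

test_that("a planted sigma ratio is detected while mu and tau stay null", {
  set.seed(64)
  pools <- make_param_pools(25, 300, sigma_ratio = 1.5)
  cmp <- compare_states(pools, "1", "2")
  tb <- cmp$table
  expect_lt(tb$p_value[tb$parameter == "sigma"], 0.05)
  expect_gt(tb$p_value[tb$parameter == "mu"], 0.05)
  expect_gt(tb$p_value[tb$parameter == "tau"], 0.05)
  # State2 direction: larger sigma in the second pool
  expect_lt(tb$mean_a[tb$parameter == "sigma"],
            tb$mean_b[tb$parameter == "sigma"])
})

test_that("the sigma test is calibrated under the null and gains power with the ratio", {
  # type-I error at the 5% level across simulated null experiments
  set.seed(65)
  n_experiments <- 400
  rejections <- replicate(n_experiments, {
    pools <- make_param_pools(12, 120, sigma_ratio = 1)
    cmp <- tryCatch(compare_states(pools, "1", "2"),
                    gradstate_no_result = function(e) NULL)
    if (is.null(cmp)) NA else cmp$table$p_value[2] < 0.05
  })
  rate <- mean(rejections, na.rm = TRUE)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)

  # power is non-decreasing in the planted ratio (common random numbers)
  ratios <- c(1.0, 1.25, 1.5, 2.0)
  power <- vapply(ratios, function(r) {
    mean(vapply(1:40, function(rep) {
      set.seed(1000 + rep)          # same draws across ratios
      pools <- make_param_pools(12, 120, sigma_ratio = r)
      cmp <- tryCatch(compare_states(pools, "1", "2"),
                      gradstate_no_result = function(e) NULL)
      if (is.null(cmp)) NA else cmp$table$p_value[2] < 0.05
    }, logical(1)), na.rm = TRUE)
  }, numeric(1))
  # non-decreasing up to Monte-Carlo noise (rates saturate near 1 at the
  # largest ratios, where exclusion sets differ slightly across ratios)
  expect_true(all(diff(power) >= -0.05))
  expect_gt(power[4], power[1] + 0.3)
})

test_that("rank correlations and their edge cases behave", {
  expect_equal(correlate_params(1:10, (1:10)^3)$rho, 1)
  expect_equal(correlate_params(1:10, -(1:10)^3)$rho, -1)
  out <- correlate_params(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_gt(out$p_value, 0)
  expect_error(correlate_params(rep(1, 5), 1:5),
               class = "gradstate_undefined_statistic")
  expect_error(correlate_params(1:2, 2:3), "at least 3")
})

test_that("error regression matches the normal equations", {
  set.seed(66)
  params <- data.frame(mu = rnorm(50, 0.8, 0.05),
                       sigma = rlnorm(50, log(0.08), 0.3),
                       tau = rlnorm(50, log(0.05), 0.3))

  exact <- regress_errors(params, 2 * params$mu)
  expect_equal(exact$coefficients$estimate, c(0, 2, 0, 0), tolerance = 1e-8)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  # independent outcome: R^2 near zero at large n
  big <- data.frame(mu = rnorm(5000), sigma = rlnorm(5000),
                    tau = rlnorm(5000))
  noise_fit <- regress_errors(big, rnorm(5000))
  expect_lt(noise_fit$r_squared, 0.01)

  # five-point fixture against an independently solved system
  p5 <- data.frame(mu = c(1, 2, 3, 4, 5), sigma = c(2, 1, 4, 3, 6),
                   tau = c(1, 3, 2, 5, 4))
  y5 <- c(3, 4, 8, 9, 14)
  X <- cbind(1, as.matrix(p5))
  beta_hand <- solve(t(X) %*% X, t(X) %*% y5)
  fit5 <- regress_errors(p5, y5)
  expect_equal(fit5$coefficients$estimate, as.numeric(beta_hand),
               tolerance = 1e-10)

  # collinear predictors fall back to the pseudo-inverse with a warning
  p_coll <- data.frame(mu = 1:6, sigma = (1:6) * 2, tau = rnorm(6))
  expect_warning(regress_errors(p_coll, rnorm(6)), "collinear")
})

test_that("mind-wandering correlation validates probes and finds planted links", {
  set.seed(67)
  sigma <- rlnorm(40, log(0.08), 0.3)
  probes <- pmin(100, pmax(0, 50 + 300 * (sigma - 0.08) + rnorm(40, 0, 5)))
  out <- mind_wandering_correlation(sigma, probes)
  expect_gt(out$rho, 0.3)

  expect_error(mind_wandering_correlation(sigma, c(probes[-1], 101)), "0, 100")
  expect_error(mind_wandering_correlation(sigma, rep(0, 40)),
               class = "gradstate_undefined_statistic")

  # probe lists are averaged per participant
  lists <- lapply(probes, function(p) c(p - 1, p + 1))
  out2 <- mind_wandering_correlation(sigma, lists)
  expect_equal(out2$rho, out$rho)
})
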
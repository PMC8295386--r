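test_that("trial streams respect the category mix and no-repeat rule", {
  big <- gen_trial_stream(10000, 0.8, 0.10, seed = 30)
  expect_lt(abs(mean(big$category == "mountain") - 0.10), 0.01)
  expect_equal(big$onset, (0:9999) * 0.8)

  tiny <- gen_trial_stream(2, 0.8, 0, seed = 31)
  expect_equal(tiny$category, c("city", "city"))
  expect_false(tiny$scene_id[1] == tiny$scene_id[2])
  expect_equal(tiny$onset, c(0, 0.8))

  slow <- gen_trial_stream(1000, 1.3, 0.10, seed = 32)
  expect_equal(sum(slow$scene_id[-1] == slow$scene_id[-1000]), 0L)

  expect_error(gen_trial_stream(1, 0.8), "at least 2")
  expect_error(gen_trial_stream(10, -1), "positive")
})

test_that("the Metropolis sampler has the Boltzmann stationary law", {
  # zero model: all patterns equally likely; with 256 bins the largest of
  # 256 z-scores concentrates near 3, so allow a 4.5-sigma envelope and
  # require near-total mass within 3
  m0 <- mem_model(rep(0, 8), matrix(0, 8, 8))
  net <- gen_network_series(m0, 100000, 50, seed = 33)
  f <- tabulate(gradstate:::patterns_to_codes(net$binary) + 1L, 256) / 1e5
  se <- sqrt((1 / 256) * (1 - 1 / 256) / 1e5)
  z <- abs(f - 1 / 256) / se
  expect_gt(mean(z < 3), 0.98)
  expect_true(all(z < 4.5))

  # total-variation stationarity against exhaustive enumeration
  m1 <- random_mem_model(6, scale = 0.5, seed = 34)
  net1 <- gen_network_series(m1, 200000, 30, seed = 35)
  emp <- tabulate(gradstate:::patterns_to_codes(net1$binary) + 1L, 64) / 2e5
  expect_lt(sum(abs(emp - pattern_probabilities(m1))) / 2, 0.01)

  # planted two-minimum model: the minima are the two most frequent patterns
  m2 <- planted_two_state_model()
  net2 <- gen_network_series(m2, 20000, 10, seed = 36)
  freq <- tabulate(gradstate:::patterns_to_codes(net2$binary) + 1L, 256)
  top2 <- order(freq, decreasing = TRUE)[1:2] - 1L
  expect_setequal(top2, unname(attr(m2, "templates")))
  # and exhaustive enumeration agrees they carry the most probability
  p <- pattern_probabilities(m2)
  expect_setequal(order(p, decreasing = TRUE)[1:2] - 1L,
                  unname(attr(m2, "templates")))

  one <- gen_network_series(m2, 1, seed = 37)
  expect_equal(dim(one$binary), c(1L, 8L))
  expect_true(all(one$binary %in% 0:1))
  expect_error(gen_network_series(m2, 0), "at least 1")
})

test_that("behavior generation honors degenerate rates and recovers moments", {
  m <- planted_two_state_model()
  ls <- energy_landscape(m)
  code1 <- ls$minima[1]
  sp <- setNames(list(list(mu = 0.80, sigma = 0.08, tau = 0.05,
                           omission_rate = 0, commission_rate = 0)),
                 as.character(code1))

  stream <- gen_trial_stream(5000, 0.8, 0.10, seed = 40)
  states <- rep(code1, ceiling((5000 * 0.8 + 5) / 2) + 1)
  beh <- gen_behavior(stream, states, sp, tr = 2, seed = 41)

  n_city <- sum(stream$category == "city")
  expect_equal(sum(beh$truth$responded), n_city)
  expect_true(all(!beh$truth$responded[beh$truth$category == "mountain"]))
  expect_equal(length(beh$presses), n_city)

  rts <- beh$truth$true_rt[beh$truth$responded]
  expect_lt(abs(mean(rts) - 0.85), 0.01)
  expect_lt(abs(var(rts) - 0.0089) / 0.0089, 0.20)

  # multipress: every responded trial gets at least two presses
  beh2 <- gen_behavior(stream[1:100, ], states, sp, tr = 2,
                       multipress_rate = 1, seed = 42)
  expect_equal(length(beh2$presses), 2 * sum(beh2$truth$responded))

  expect_error(gen_behavior(stream, integer(0), sp, tr = 2), "empty")
  expect_error(gen_behavior(stream, states[1:10], sp, tr = 2), "cover")
})

test_that("the assignment stage reconstructs noise-free generated RTs exactly", {
  m <- planted_two_state_model()
  ls <- energy_landscape(m)
  code1 <- ls$minima[1]
  sp <- setNames(list(list(mu = 0.80, sigma = 0.05, tau = 0.03,
                           omission_rate = 0, commission_rate = 0)),
                 as.character(code1))
  stream <- gen_trial_stream(500, 0.8, 0.10, seed = 43)
  states <- rep(code1, 250)
  beh <- gen_behavior(stream, states, sp, tr = 2, seed = 44)
  out <- assign_presses(stream, beh$presses)
  city <- stream$category == "city"
  expect_equal(out$rt[city], beh$truth$true_rt[city])
  expect_true(all(out$classification[city] == "correct_commission"))
})

test_that("population draws honor degenerate spreads and planted correlations", {
  flat <- gen_population(10, sds = c(mu = 0, sigma = 0, tau = 0), seed = 50)
  expect_equal(flat$mu, rep(0.80, 10))
  expect_equal(flat$sigma, rep(0.08, 10))
  expect_equal(flat$tau, rep(0.05, 10))

  pop <- gen_population(5000, rho_omission = c(sigma = 0.5), seed = 51)
  rec <- correlate_params(pop$sigma, pop$omission_rate)
  expect_lt(abs(rec$rho - 0.5), 0.05)
  expect_true(all(pop$sigma > 0) && all(pop$tau > 0))
  expect_true(all(pop$omission_rate >= 0 & pop$omission_rate <= 1))

  single <- gen_population(1, seed = 52)
  expect_equal(nrow(single), 1L)
  expect_true(single$sigma > 0 && single$tau > 0)

  expect_error(gen_population(5, sds = c(mu = -1, sigma = 0, tau = 0)),
               "non-negative")
  expect_error(gen_population(5, rho_omission = c(sigma = 0.9, tau = 0.9)),
               "too strong")
})

test_that("simulation is reproducible from the master seed", {
  cfg <- list(seed = 7, n_participants = 2, n_runs = 1, n_trials_per_run = 60)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$population, b$population)

  cfg2 <- cfg; cfg2$seed <- 8
  c2 <- simulate_dataset(cfg2)
  expect_false(identical(a$participants, c2$participants))
})

test_that("dataset export writes events, networks and ground truth", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(list(seed = 9, n_participants = 1, n_runs = 1,
                               n_trials_per_run = 50), dir = dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  ev_path <- file.path(dir, "sub-01", "sub-01_run-01_events.tsv")
  expect_true(file.exists(ev_path))
  ev <- read_events(ev_path)
  expect_equal(nrow(ev), 50L)
  expect_equal(ev$onset, sim$participants[[1]][[1]]$stream$onset)
  expect_true(all(c("onset", "duration", "trial_type", "scene_id",
                    "response_time") %in% names(ev)))
})
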
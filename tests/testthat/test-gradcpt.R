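test_that("coherence follows the linear cross-fade convention", {
  expect_equal(rt_to_coherence(0.72, 0.8),
               c(current = 0.9, previous = 0.1, next. = 0))
  expect_equal(rt_to_coherence(0.8, 0.8)[["current"]], 1)
  expect_equal(rt_to_coherence(0.4, 0.8),
               c(current = 0.5, previous = 0.5, next. = 0))
  expect_equal(rt_to_coherence(1.17, 1.3),
               c(current = 0.9, previous = 0.1, next. = 0))
  expect_equal(rt_to_coherence(1.2, 0.8)[["next."]], 0.5)
  expect_error(rt_to_coherence(1.7, 0.8), "outside")
  expect_error(rt_to_coherence(1, 0), "positive")
})

test_that("in-window presses stay with their trials and classify correctly", {
  st <- trial_stream(rep("city", 3), isi = 0.8)
  out <- assign_presses(st, c(0.6, 1.4, 2.2))
  expect_equal(out$rt, rep(0.6, 3))
  expect_true(all(out$classification == "correct_commission"))

  # unassigned-mountain / omission classifications
  st2 <- trial_stream(c("city", "mountain", "city"), isi = 0.8)
  out2 <- assign_presses(st2, c(0.6, 1.4))
  expect_equal(out2$classification,
               c("correct_commission", "commission_error", "omission_error"))
  expect_error(assign_presses(st, c(1.4, 0.6)), "sorted")
})

test_that("a second press on a responded trial moves to an empty neighbor", {
  # press 0.9 answers trial 1; second press at rt 1.2*isi = 0.96 is surplus
  # and trial 2 has no response, so it becomes trial 2's (fast) response
  st <- trial_stream(rep("city", 3), isi = 0.8)
  out <- assign_presses(st, c(0.9, 0.96, 2.2))
  expect_equal(out$rt[1], 0.9)
  expect_equal(out$rt[2], 0.96 - 0.8)
  expect_equal(out$classification[2], "correct_commission")
})

test_that("multiple presses on one trial keep the fastest", {
  st <- trial_stream(rep("city", 2), isi = 0.8)
  # both presses unambiguous for trial 1 (rts 0.58, 0.90); trial 2 takes the
  # surplus; then add a third press so trial 2 is already occupied
  out <- assign_presses(st, c(0.58, 0.90, 1.5))
  expect_equal(out$rt[1], 0.58)
  expect_equal(out$rt[2], 1.5 - 0.8)
  # with trial 2 occupied, the surplus press is dropped entirely
  expect_equal(attr(out, "n_unassigned"), 1L)
})

test_that("ambiguous presses between two empty trials go to the closer one, sparing mountains", {
  # press in the gap between windows of trials 1 and 2: at 1.25 with isi 0.8
  # (window of 1 ends 1.12, window of 2 starts 1.36); distances to full
  # coherence: |1.25 - 0.8| = 0.45 vs |1.25 - 1.6| = 0.35 -> trial 2
  st <- trial_stream(rep("city", 2), isi = 0.8)
  out <- assign_presses(st, 1.25)
  expect_true(is.na(out$rt[1]))
  expect_equal(out$rt[2], 1.25 - 0.8)

  # same press, but trial 2 is a mountain: benefit of the doubt -> trial 1
  st_m <- trial_stream(c("city", "mountain"), isi = 0.8)
  out_m <- assign_presses(st_m, 1.25)
  expect_equal(out_m$rt[1], 1.25)
  expect_equal(out_m$classification[2], "correct_omission")

  # if exactly one neighbor is empty the press goes there
  st3 <- trial_stream(rep("city", 2), isi = 0.8)
  out3 <- assign_presses(st3, c(0.9, 1.25))
  expect_equal(out3$rt[2], 1.25 - 0.8)
})

test_that("error counts partition trials and recover planted rates", {
  st <- trial_stream(c(rep("city", 9), "mountain"), isi = 0.8)
  out <- assign_presses(st, st$onset[1:10] + 0.8)
  cnt <- error_counts(out)
  expect_equal(cnt$omission, 0)
  expect_equal(cnt$commission, 1)
  expect_equal(cnt$commission_rate, 1.0)
  expect_equal(cnt$omission + cnt$commission + cnt$correct_commission +
                 cnt$correct_omission, 10)

  # generator round trip with planted rates
  model <- planted_two_state_model()
  landscape <- energy_landscape(model)
  stream <- gen_trial_stream(10000, 0.8, 0.10, seed = 5)
  states <- rep(landscape$minima[1], ceiling((10000 * 0.8 + 5) / 2) + 1)
  sp <- setNames(list(list(mu = 0.8, sigma = 0.05, tau = 0.04,
                           omission_rate = 0.05, commission_rate = 0.3)),
                 as.character(landscape$minima[1]))
  beh <- gen_behavior(stream, states, sp, tr = 2, seed = 6)
  cnt2 <- error_counts(assign_presses(stream, beh$presses))
  expect_lt(abs(cnt2$omission_rate - 0.05), 0.01)
  expect_lt(abs(cnt2$commission_rate - 0.3), 0.03)
})

test_that("tune-out gaps of 30 s or more flag the run", {
  st <- trial_stream(rep("city", 100), isi = 0.8)
  out <- assign_presses(st, st$onset + 0.8)
  expect_false(exclude_tuneouts(out))

  # silence the middle stretch to open a >= 30 s gap
  broken <- out
  broken$rt[20:60] <- NA
  expect_true(exclude_tuneouts(broken))

  # boundary: a gap of exactly the window length flags
  st2 <- trial_stream(rep("city", 2), isi = 0.8)
  two <- assign_presses(st2, c(0.8, 1.6))
  expect_true(exclude_tuneouts(two, window = 30, run_end = 31.6))
  expect_false(exclude_tuneouts(two, window = 30, run_end = 31))
})

test_that("assignments are valid and deterministic on random toy instances", {
  for (seed in 1:200) {
    inst <- random_toy_instance(seed)
    out <- assign_presses(inst$stream, inst$presses)
    used <- out$press_index[!is.na(out$press_index)]
    expect_equal(anyDuplicated(used), 0L)
    # a trial whose window holds exactly one press keeps that press
    isi <- attr(inst$stream, "isi")
    for (t in seq_len(nrow(out))) {
      inwin <- which(inst$presses >= inst$stream$onset[t] + 0.7 * isi &
                       inst$presses <= inst$stream$onset[t] + 1.4 * isi)
      if (length(inwin) == 1) expect_identical(out$press_index[t], inwin)
    }
    out2 <- assign_presses(inst$stream, inst$presses)
    expect_identical(out, out2)
  }
})
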
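test_that("sensor arrays satisfy their geometric contract", {
  arr <- make_sensor_array(275L, 120, seed = 7L)
  expect_length(arr$channel_ids, 275L)
  expect_equal(sqrt(rowSums(arr$orientations^2)), rep(1, 275), tolerance = 1e-9)
  expect_true(all(sqrt(rowSums(arr$positions^2)) > 100))  # outside the conductor
  # deterministic for a fixed seed, distinct for another
  expect_identical(arr, make_sensor_array(275L, 120, seed = 7L))
  expect_false(identical(arr$positions, make_sensor_array(275L, 120, seed = 8L)$positions))
  # minimal valid array and the configuration error below it
  expect_length(make_sensor_array(4L, 120, seed = 1L)$channel_ids, 4L)
  expect_error(make_sensor_array(3L, 120, seed = 1L), "n_channels")
})

test_that("noise-free simulation equals lead field times source time course", {
  arr <- make_sensor_array(8L, 120, seed = 1L)
  spec <- simulation_spec(matrix(c(30, 40, 30), 1L), matrix(c(1, 9), 1L),
                          duration_s = 10, rate_hz = 1000, noise_sd = 0, seed = 2L)
  sim <- simulate_recording(spec, arr)
  predicted <- sim$truth$gains %*% sim$truth$source_signals
  expect_lt(max(abs(sim$recording$data - predicted)) / max(abs(predicted)), 1e-10)
  # silence outside the seizure window
  expect_equal(max(abs(sim$recording$data[, 1:900])), 0)
})

test_that("simulated sources are band-limited and spike at the discharge rate", {
  arr <- make_sensor_array(8L, 120, seed = 1L)
  spec <- simulation_spec(matrix(c(30, 40, 30), 1L), matrix(c(1, 9), 1L),
                          duration_s = 10, rate_hz = 1000, noise_sd = 0, seed = 2L)
  sim <- simulate_recording(spec, arr)
  s <- sim$truth$source_signals[1L, 1001:9000]
  pw <- abs(fft(s))^2
  f <- (seq_along(s) - 1) * 1000 / length(s)
  half <- f <= 500
  in_band <- half & f >= spec$source_band[1L] & f <= spec$source_band[2L]
  expect_gte(sum(pw[in_band]) / sum(pw[half]), 0.90)
  # dominant spectral line sits at the 3 Hz discharge rate
  expect_equal(f[half][which.max(pw[half] * (f[half] > 0.5))], 3, tolerance = 0.2)
})

test_that("artifact windows reach their stated amplitude", {
  arr <- make_sensor_array(16L, 120, seed = 1L)
  spec <- simulation_spec(matrix(c(30, 40, 30), 1L), matrix(c(2, 6), 1L),
                          duration_s = 8, rate_hz = 1000, snr = 5,
                          artifact_windows = matrix(c(6.5, 7.5, 7e-12), 1L),
                          seed = 5L)
  sim <- simulate_recording(spec, arr)
  win <- sim$recording$data[, 6501:7500]
  expect_gt(max(abs(win)), 6e-12)
  expect_lt(max(abs(sim$recording$data[, 1:1500])), 6e-12)
})

test_that("the seed contract holds: distinct noise, identical seizure timing", {
  arr <- make_sensor_array(8L, 120, seed = 1L)
  mk <- function(seed) {
    spec <- simulation_spec(matrix(c(30, 40, 30), 1L), matrix(c(2, 6), 1L),
                            duration_s = 8, rate_hz = 1000, snr = 5, seed = seed)
    simulate_recording(spec, arr)
  }
  a <- mk(1L); b <- mk(2L)
  expect_false(identical(a$recording$data, b$recording$data))
  expect_identical(a$truth$segment_boundaries, b$truth$segment_boundaries)
  expect_identical(mk(1L)$recording$data, a$recording$data)  # reproducible
})

test_that("simulation_spec rejects invalid configurations", {
  loc <- matrix(c(30, 40, 30), 1L)
  expect_error(simulation_spec(loc, matrix(c(5, 4), 1L)), "seizure windows")
  expect_error(simulation_spec(loc, matrix(c(1, 3, 2, 5), 2L, byrow = TRUE)),
               "disjoint")
  expect_error(simulation_spec(loc, matrix(c(1, 3), 1L), rate_hz = 60),
               "rate_hz")
})

test_that("cohorts have the requested structure and derivable group labels", {
  co <- make_cohort(13L, 11L, seed = 1L, simulate = FALSE)
  expect_length(co$patients, 24L)
  expect_equal(as.integer(table(co$records$group)), c(13L, 11L))
  # group labels are recovered from the clinical fields, never hand-set
  expect_identical(classify_response(co$records),
                   co$records$group)
  # boundary: smallest smoke-test cohort, with recordings
  co2 <- make_cohort(2L, 2L, seed = 1L, duration_s = 6, seizure_s = 3.2)
  expect_length(co2$patients, 4L)
  expect_s3_class(co2$patients[[1L]]$recording, "meg_recording")
  expect_error(make_cohort(0L, 2L), "group sizes")
})

test_that("effect strength 0 collapses both groups onto one placement distribution", {
  eff <- cohort_effect(strength = 0)
  expect_equal(eff$p_roi_nonresp, eff$p_roi_resp)
  co <- make_cohort(6L, 6L, effect = eff, seed = 2L, simulate = FALSE)
  expect_equal(as.integer(table(co$records$group)), c(6L, 6L))
})

test_that("null cohorts give a calibrated (super-uniform) Fisher test", {
  # Fisher's exact p on sparse 11-vs-13 tables is discrete and
  # conservative; the correct calibration property is super-uniformity,
  # and the attained alpha=0.05 rate has an exactly enumerable oracle.
  n_rep <- 300L
  eff <- cohort_effect(strength = 0)
  grid <- tiny_grid(); atlas <- tiny_atlas()
  ps <- vapply(seq_len(n_rep), function(s) {
    co <- make_cohort(13L, 11L, effect = eff, seed = s, grid = grid,
                      atlas = atlas, simulate = FALSE)
    truth_region <- vapply(co$patients, function(p) p$truth$region, character(1L))
    tab <- build_contingency(co$records$group, truth_region, "MFC")
    fisher_exact(tab)
  }, numeric(1L))
  for (a in c(0.01, 0.05, 0.1, 0.5)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / n_rep))
  }
  # exact oracle for the attained rate at alpha = 0.05: enumerate both
  # placement binomials at p_roi = 0.05
  exact <- 0
  for (a in 0:11) for (cc in 0:13) {
    p <- fisher_oracle(a, 11L - a, cc, 13L - cc)
    if (p < 0.05)
      exact <- exact + dbinom(a, 11L, eff$p_roi_nonresp) * dbinom(cc, 13L, eff$p_roi_resp)
  }
  expect_lt(abs(mean(ps < 0.05) - exact), 3 * sqrt(max(exact, 1 / n_rep) / n_rep) + 1 / n_rep)
})
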
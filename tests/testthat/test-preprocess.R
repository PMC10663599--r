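test_that("global signal is the masked pixel sum and is linear", {
  frames <- array(1, dim = c(5, 4, 4))
  mask <- matrix(FALSE, 4, 4)
  mask[cbind(c(1, 1, 2, 2, 3), c(1, 2, 1, 2, 3))] <- TRUE
  expect_equal(global_signal(frames, mask), rep(5, 5))
  a <- array(stats::rnorm(5 * 16), dim = c(5, 4, 4))
  b <- array(stats::rnorm(5 * 16), dim = c(5, 4, 4))
  expect_equal(global_signal(a + b, mask),
               global_signal(a, mask) + global_signal(b, mask))
  expect_error(global_signal(frames, matrix(FALSE, 4, 4)),
               class = "eitcpr_invalid_argument")
  sim <- quiet_sim(duration_s = 18, noise_sd = 0)
  expect_equal(global_signal(sim$recording), sim$truth$global_clean)
})

test_that("artifact filter passes breathing and suppresses compressions", {
  fs <- FS_EIT
  t <- seq(0, 120, by = 1 / fs)
  resp <- sin(2 * pi * (1 / 6) * t)
  ccart <- sin(2 * pi * 1.7 * t)
  i <- t > 15 & t < 105  # away from edges
  rf <- remove_cc_artifact(resp, fs)
  expect_gt(diff(range(rf[i])) / 2, 0.95)           # passband gain
  cf <- remove_cc_artifact(ccart, fs)
  expect_lt(diff(range(cf[i])) / 2, 0.1)            # >= 10x attenuation
  # linearity and zero phase: extrema of a passband signal do not move
  expect_equal(remove_cc_artifact(3 * resp, fs), 3 * rf)
  expect_lt(abs(which.max(rf[i]) - which.max(resp[i])), 2)
  # infeasible band separation is refused with a diagnostic
  expect_error(remove_cc_artifact(resp, fs, resp_rate_per_min = 40,
                                  cc_rate_per_min = 102),
               class = "eitcpr_infeasible_filter")
})

test_that("filtering frames commutes with the global sum", {
  sim <- quiet_sim(duration_s = 18, noise_sd = 0.3, seed = 2)
  rec <- sim$recording
  ff <- remove_cc_artifact(rec$frames, rec$fs_hz)
  expect_equal(global_signal(ff, rec$mask),
               remove_cc_artifact(global_signal(rec), rec$fs_hz),
               tolerance = 1e-8)
})

test_that("per-breath tidal amplitude is recovered through the filter", {
  sim <- cc_sim(subject_params(noise_sd = 0.5), seed = 11)
  gf <- remove_cc_artifact(global_signal(sim$recording), FS_EIT)
  br <- segment_breaths(gf, FS_EIT)
  # breaths after the end-expiratory level has stabilized (drift tau 10 s)
  inside <- br[br$onset_s >= 56 & br$onset_s < 84, ]
  expect_true(all(abs(inside$vt_eit_au - sim$truth$vt_eit_au) /
                    sim$truth$vt_eit_au < 0.05))
})

test_that("compression windows are detected within a second", {
  sim <- cc_sim(subject_params(noise_sd = 0.5), cc_windows = cbind(60, 120),
                duration_s = 180, seed = 3)
  w <- detect_cc_windows(global_signal(sim$recording), FS_EIT)
  expect_equal(nrow(w), 1)
  expect_lt(abs(w[1, 1] - 60), 1)
  expect_lt(abs(w[1, 2] - 120), 1)
  # two bouts -> two windows
  sim2 <- cc_sim(subject_params(noise_sd = 0.5),
                 cc_windows = rbind(c(30, 60), c(100, 130)),
                 duration_s = 160, seed = 4)
  w2 <- detect_cc_windows(global_signal(sim2$recording), FS_EIT)
  expect_equal(nrow(w2), 2)
  # no compressions -> nothing detected
  sim3 <- quiet_sim(duration_s = 60, noise_sd = 0.5, seed = 5)
  expect_equal(nrow(detect_cc_windows(global_signal(sim3$recording), FS_EIT)), 0)
  expect_error(detect_cc_windows(stats::rnorm(10), FS_EIT),
               class = "eitcpr_invalid_argument")
})

test_that("breath segmentation finds the annotated cycles", {
  # unfiltered noiseless signal: onsets exact to two frames (the frame grid
  # is incommensurate with the cycle, and the signal is almost flat at the
  # expiratory minimum, so neighbouring frames can tie numerically)
  sim0 <- quiet_sim(duration_s = 70, noise_sd = 0, seed = 2)
  br0 <- segment_breaths(global_signal(sim0$recording), FS_EIT)
  for (o in br0$onset_s) {
    expect_lt(min(abs(sim0$truth$onsets_s - o)), 2.5 / FS_EIT)
  }
  # through the zero-phase filter the smoothed corner moves the minimum by
  # at most ~2 frames
  sim <- quiet_sim(duration_s = 70, noise_sd = 0.1, seed = 2)
  gf <- remove_cc_artifact(global_signal(sim$recording), FS_EIT)
  br <- segment_breaths(gf, FS_EIT)
  for (o in br$onset_s) {
    expect_lt(min(abs(sim$truth$onsets_s - o)), 3.5 / FS_EIT)
  }
  # 60-s windows hold 10 cycles at 10 breaths/min
  t0 <- br$onset_s[1]
  expect_equal(sum(br$onset_s >= t0 - 1e-9 & br$onset_s < t0 + 60 - 1e-9), 10)
  # monotone ramp: no breaths, not an error
  expect_equal(nrow(segment_breaths(seq(0, 1, length.out = 200), FS_EIT)), 0)
})

test_that("breath counts match truth across randomized seeds", {
  for (seed in 1:5) {
    dur <- 30 + 6 * seed
    sim <- quiet_sim(duration_s = dur, noise_sd = 0.4, seed = seed)
    gf <- remove_cc_artifact(global_signal(sim$recording), FS_EIT)
    br <- segment_breaths(gf, FS_EIT)
    # away from the recording edges every cycle is found exactly once
    interior <- sim$truth$onsets_s[sim$truth$onsets_s >= 6 &
                                     sim$truth$onsets_s <= dur - 12]
    got <- br$onset_s[br$onset_s > 3 & br$onset_s <= dur - 9]
    expect_equal(length(got), length(interior))
    expect_true(all(vapply(interior, function(o) min(abs(got - o)), 1) < 0.3))
  }
})
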
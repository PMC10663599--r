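test_that("ventilator breaths are segmented at the generator timing", {
  sig <- simulate_pressure_flow(subject_params(), n_breaths = 3, seed = 1)
  br <- segment_vent_breaths(sig)
  expect_equal(nrow(br), 3)
  # 6-s cycle at 200 Hz -> 1200 samples between successive inspirations
  expect_equal(diff(br$insp_start_idx), rep(1200, 2))
  # inspiration start within 1 sample of the programmed onset
  expect_lt(abs(sig$time_s[br$insp_start_idx[1]] - 0.5), 2 / sig$fs_hz)
  expect_true(all(br$has_pause))
  # ventilation without a usable end-inspiratory hold: all breaths flagged
  vent_np <- ventilator_settings(t_pause_s = 0.05, t_expiration_s = 4.95)
  sig_np <- simulate_pressure_flow(subject_params(), vent_np,
                                   n_breaths = 3, seed = 1)
  expect_warning(br2 <- segment_vent_breaths(sig_np), class = "eitcpr_no_pause")
  expect_false(any(br2$has_pause))
  # breaths overlapping compression windows are excluded
  br3 <- segment_vent_breaths(sig, cc_windows = cbind(0, 7))
  expect_true(br3$excluded[1] && !br3$excluded[3])
})

test_that("compliance recovers the injected mechanics exactly when noiseless", {
  sp <- subject_params(lung_compliance_ml_cmH2O = 50,
                       chestwall_compliance_ml_cmH2O = 100)
  cm <- compliance(simulate_pressure_flow(sp, n_breaths = 3, seed = 1))
  cm <- cm[cm$valid, ]
  expect_equal(cm$c_lung_ml_cmH2O, rep(50, 3), tolerance = 0.02)
  expect_equal(cm$c_cw_ml_cmH2O, rep(100, 3), tolerance = 0.02)
  # elastance additivity: 1/Crs = 1/CL + 1/Ccw within 2%
  expect_equal(1 / cm$c_rs_ml_cmH2O, 1 / cm$c_lung_ml_cmH2O + 1 / cm$c_cw_ml_cmH2O,
               tolerance = 0.02)
  # plateau >= end-expiratory pressures on passive breaths
  expect_true(all(cm$paw_plateau_cmH2O >= cm$paw_ee_cmH2O))
  # no esophageal trace: C_L and C_CW missing, C_rs still present
  cm2 <- compliance(simulate_pressure_flow(sp, n_breaths = 2, seed = 1,
                                           include_pes = FALSE))
  cm2 <- cm2[cm2$valid, ]
  expect_true(all(is.na(cm2$c_lung_ml_cmH2O)) && all(is.na(cm2$c_cw_ml_cmH2O)))
  expect_equal(cm2$c_rs_ml_cmH2O, rep(1 / (1 / 50 + 1 / 100), 2), tolerance = 0.02)
})

test_that("compliance error stays below 5% under waveform noise", {
  errs <- vapply(1:6, function(seed) {
    sig <- simulate_pressure_flow(subject_params(), n_breaths = 4,
                                  seed = seed, noise_frac = 0.05)
    cm <- compliance(sig)
    stats::median(abs(cm$c_lung_ml_cmH2O[cm$valid] - 50) / 50, na.rm = TRUE)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("before/after compression compliance change is recovered with CI", {
  mk_side <- function(cl_values) {
    do.call(rbind, lapply(seq_along(cl_values), function(i) {
      sp <- subject_params(lung_compliance_ml_cmH2O = cl_values[i])
      cm <- compliance(simulate_pressure_flow(sp, n_breaths = 2, seed = i,
                                              noise_frac = 0.01))
      cbind(subject = i, cm[cm$valid, , drop = FALSE])
    }))
  }
  set.seed(41)
  base <- 50 + stats::rnorm(5, 0, 4)
  before <- mk_side(base)
  after <- mk_side(base + 6)           # +6 ml/cmH2O after compressions
  ch <- compliance_change(before, after, "c_lung_ml_cmH2O")
  expect_gt(ch$estimate, 0)            # positive = greater after compressions
  expect_true(ch$ci[1] <= 6 && 6 <= ch$ci[2])
  # identical sides: change ~ 0 and the CI covers 0
  ch0 <- compliance_change(before, before, "c_lung_ml_cmH2O")
  expect_equal(ch0$estimate, 0, tolerance = 1e-9)
  expect_true(ch0$ci[1] <= 0 && 0 <= ch0$ci[2])
  expect_error(compliance_change(before[0, ], after, "c_lung_ml_cmH2O"),
               class = "eitcpr_invalid_argument")
})
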
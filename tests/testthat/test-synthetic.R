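test_that("protocol assigns every sequence once per subject, reproducibly", {
  pd <- make_protocol(7, seed = 1)
  expect_equal(nrow(pd$assignments), 35)
  for (i in 1:7) {
    expect_setequal(pd$assignments$sequence[pd$assignments$subject == i],
                    eitcpr_sequences())
  }
  pd1 <- make_protocol(3, seed = 42)
  pd2 <- make_protocol(3, seed = 42)
  expect_identical(pd1$assignments, pd2$assignments)
  expect_false(identical(make_protocol(3, seed = 43)$assignments,
                         pd1$assignments))
  expect_error(make_protocol(0), class = "eitcpr_invalid_argument")
})

test_that("protocol timeline keeps the fixed inclination order and CC plan", {
  segs <- protocol_segments()
  expect_true(all(diff(segs$angle_start) >= 0))
  # compressions: 1 min flat, then one continuous bout 18 deg -> ramp -> 35 deg
  ccw <- eitcpr:::segments_cc_windows(segs)
  expect_equal(nrow(ccw), 2)
  expect_equal(unname(ccw[1, 2] - ccw[1, 1]), 60)
  expect_equal(unname(ccw[2, 2] - ccw[2, 1]), 60 + 120 + 90)
})

test_that("generator is deterministic and respects its preconditions", {
  s1 <- quiet_sim(noise_sd = 0.5, seed = 9)
  s2 <- quiet_sim(noise_sd = 0.5, seed = 9)
  expect_identical(s1$recording$frames, s2$recording$frames)
  s3 <- quiet_sim(noise_sd = 0.5, seed = 10)
  expect_false(identical(s1$recording$frames, s3$recording$frames))

  expect_error(simulate_eit_recording(small_subject(), fs_hz = 3,
                                      cc = compression_settings(windows = cbind(5, 20)),
                                      duration_s = 30),
               class = "eitcpr_invalid_argument")
  expect_error(simulate_eit_recording(small_subject(), duration_s = 2),
               class = "eitcpr_invalid_argument")
})

test_that("noiseless global amplitude equals the summed tidal amplitudes", {
  sim <- quiet_sim(duration_s = 18, noise_sd = 0,
                   pendelluft_fraction = 0, max_delay_frac = 0)
  g <- global_signal(sim$recording)
  # interior cycle: frames within [6, 12) s
  rec_t <- (seq_along(g) - 1) / FS_EIT
  idx <- which(rec_t >= 6 & rec_t < 12)
  # exact up to one sample of waveform discretization (the frame grid is
  # incommensurate with the 6-s cycle, so the sampled minimum can sit up to
  # one frame after the true cycle end)
  expect_lt(abs(diff(range(g[idx])) - sim$truth$vt_eit_au),
            sim$truth$vt_eit_au / FS_EIT)
  expect_equal(max(abs(g - sim$truth$global_clean)), 0)
})

test_that("compression artifact sits at the device rate (spectral separation)", {
  sim <- cc_sim(subject_params(noise_sd = 0), cc_windows = cbind(10, 70),
                duration_s = 80)
  g <- global_signal(sim$recording)
  i <- (round(10 * FS_EIT) + 1):(round(70 * FS_EIT))
  seg <- g[i] - mean(g[i])
  sp <- Mod(stats::fft(seg))^2
  fr <- (seq_along(seg) - 1) * FS_EIT / length(seg)
  band <- fr >= 1 & fr <= 3
  peak_hz <- fr[band][which.max(sp[band])]
  expect_lt(abs(peak_hz - 102 / 60), FS_EIT / length(seg) + 1e-12)
})

test_that("pendelluft pixels carry the requested share of tidal impedance", {
  sp <- small_subject(pendelluft_fraction = 0.10)
  signed <- eitcpr:::subject_signed_map(sp)
  v <- signed[sp$mask]
  expect_equal(100 * sum(v[v < 0]) / sum(v), -10, tolerance = 1e-9)
})

test_that("pressure/flow generator matches the single-compartment closed forms", {
  sp <- subject_params(lung_compliance_ml_cmH2O = 50,
                       chestwall_compliance_ml_cmH2O = 100)
  vent <- ventilator_settings(tidal_volume_ml = 400)
  sig <- simulate_pressure_flow(sp, vent, n_breaths = 2, seed = 1)
  # Pes plateau - baseline = VT / C_CW = 4 cmH2O
  ph <- (sig$time_s - 0.5) %% 6
  plateau <- ph > 1.7 & ph < 2.0 & sig$time_s > 0.5
  baseline <- sig$time_s < 0.45
  expect_equal(mean(sig$pes_cmH2O[plateau]) - mean(sig$pes_cmH2O[baseline]),
               4, tolerance = 1e-6)
  # Paw plateau - PEEP = VT / Crs
  expect_equal(mean(sig$paw_cmH2O[plateau]) - vent$peep_cmH2O,
               400 / (1 / (1 / 50 + 1 / 100)), tolerance = 1e-6)
  # 8 ml/kg at 51 kg predicted body weight delivers 408 ml
  v408 <- ventilator_settings(tidal_volume_ml = 8 * 51)
  expect_equal(v408$tidal_volume_ml, 408)
  # inspiratory flow integral equals VT within 0.1% at 200 Hz
  # (window flanked by one zero-flow sample so the edges integrate cleanly)
  insp <- sig$time_s >= 0.5 - 1 / 200 - 1e-9 & sig$time_s <= 1.5 + 1e-9
  t <- sig$time_s[insp]; f <- sig$flow_L_s[insp]
  vt_int <- sum(diff(t) * (f[-1] + f[-length(f)]) / 2) * 1000
  expect_lt(abs(vt_int - 400) / 400, 0.001)
  expect_error(simulate_pressure_flow(sp, vent, fs_hz = 20),
               class = "eitcpr_invalid_argument")
})

test_that("ventilator and compression settings enforce their invariants", {
  expect_error(ventilator_settings(rate_per_min = 12),  # 5 s cycle vs 6 s parts
               class = "eitcpr_invalid_argument")
  expect_error(ventilator_settings(peep_cmH2O = -1),
               class = "eitcpr_invalid_argument")
  expect_error(compression_settings(windows = rbind(c(0, 10), c(5, 15))),
               class = "eitcpr_invalid_argument")
  expect_error(subject_params(grid_dims = c(4, 4)),
               class = "eitcpr_invalid_argument")
})
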
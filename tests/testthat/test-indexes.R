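test_that("tidal maps conserve the global tidal change and flag antiphase", {
  # hand-built: 2 frames, 2x2 grid, one antiphase pixel
  f0 <- matrix(c(0, 0, 0, 10), 2, 2)
  f1 <- matrix(c(5, 3, 2, 0), 2, 2)
  frames <- frames_from(list(f0, f1))
  mask <- matrix(TRUE, 2, 2)
  b <- manual_breath(1, 2)
  pm <- pixel_tidal_map(frames, b, mask)
  expect_equal(sum(pm), diff(global_signal(frames, mask)))
  expect_lt(pm[2, 2], 0)
  # uniform ventilation: every pixel VT/N
  fr2 <- frames_from(list(matrix(0, 2, 2), matrix(2.5, 2, 2)))
  expect_equal(as.numeric(pixel_tidal_map(fr2, b, mask)), rep(2.5, 4))
  expect_error(pixel_tidal_map(frames, b, matrix(TRUE, 3, 3)),
               class = "eitcpr_invalid_argument")
})

test_that("vt_eit is the onset-to-maximum rise and scales linearly", {
  x <- c(0, 1, 3, 3, 2, 1, 0.5)
  b <- manual_breath(1, 3, 7)
  expect_equal(vt_eit(x, b), 3)
  expect_equal(vt_eit(2 * x, b), 6)
  expect_equal(vt_eit(rep(1, 7), b), 0)
  expect_error(vt_eit(x, manual_breath(1, 3, 20)),
               class = "eitcpr_invalid_argument")
})

test_that("anterior/posterior ratio handles symmetry and degenerate splits", {
  mask <- matrix(TRUE, 4, 2)
  mk <- function(vals) structure(matrix(vals, 4, 2), class = c("pixel_map", "matrix", "array"))
  expect_equal(ap_ratio(mk(rep(1, 8))), 1)                # mirror-symmetric
  m <- mk(c(2, 2, 1, 1, 2, 2, 1, 1))
  expect_equal(ap_ratio(m), 2)
  # all ventilation anterior: undefined, reported missing
  expect_warning(r <- ap_ratio(mk(c(1, 1, 0, 0, 1, 1, 0, 0))),
                 class = "eitcpr_undefined_ratio")
  expect_true(is.na(r))
})

test_that("pendelluft is the negative-pixel share of net tidal change", {
  mk <- function(vals) structure(matrix(vals, 2, 2), class = c("pixel_map", "matrix", "array"))
  expect_equal(pendelluft(mk(c(1, 2, 3, 4))), 0)          # all positive
  expect_equal(pendelluft(mk(c(60, 30, 20, -10))), -10)   # -10 a.u. on net 100
  expect_error(pendelluft(mk(c(-1, -2, 1, 1))), class = "eitcpr_undefined")
  # monotone: more antiphase amplitude -> strictly more negative index
  sp_small <- small_subject(pendelluft_fraction = 0.05)
  sp_big <- small_subject(pendelluft_fraction = 0.15)
  val <- function(sp) {
    sim <- simulate_eit_recording(sp, cc = compression_settings(),
                                  duration_s = 20, seed = 1)
    gf <- global_signal(sim$recording$frames, sim$recording$mask)
    br <- segment_breaths(gf, FS_EIT)
    pendelluft(pixel_tidal_map(sim$recording$frames, br[1, ], sim$recording$mask))
  }
  expect_lt(val(sp_big), val(sp_small))
  expect_equal(val(sp_small), -5, tolerance = 0.2)
})

test_that("regional delay of a linear inflation equals the threshold", {
  nfr <- 12
  frames <- frames_from(lapply(seq(0, 1, length.out = nfr),
                               function(v) matrix(v, 3, 3)))
  b <- manual_breath(1, nfr)
  rv <- rvd_map(frames, b, matrix(TRUE, 3, 3))
  expect_equal(as.numeric(rv), rep(40, 9), tolerance = 1e-12)
  expect_equal(sdrvd(rv), 0)                      # synchronous inflation
  expect_error(rvd_map(frames[1:2, , , drop = FALSE], manual_breath(1, 2),
                       matrix(TRUE, 3, 3)),
               class = "eitcpr_invalid_argument")
  # antiphase-only input leaves no pixels
  down <- frames_from(lapply(seq(1, 0, length.out = nfr),
                             function(v) matrix(v, 3, 3)))
  expect_error(rvd_map(down, b, matrix(TRUE, 3, 3)), class = "eitcpr_undefined")
})

test_that("delay statistics recover the injected delay distribution", {
  sp <- small_subject(noise_sd = 0, pendelluft_fraction = 0)
  sim <- simulate_eit_recording(sp, cc = compression_settings(),
                                duration_s = 20, seed = 1)
  g <- global_signal(sim$recording)
  br <- segment_breaths(g, FS_EIT)
  rv <- rvd_map(sim$recording$frames, br[1, ], sim$recording$mask)
  expect_equal(sdrvd(rv), sim$truth$sdrvd_pct, tolerance = 0.1)
  expect_true(all(rv[!is.na(rv)] >= 0 & rv[!is.na(rv)] <= 100))
})

test_that("inhomogeneity index matches hand computation and its identities", {
  mk <- function(vals, nr = 2, nc = 2) {
    structure(matrix(vals, nr, nc), class = c("pixel_map", "matrix", "array"))
  }
  expect_equal(gii(mk(c(1, 1, 1, 5))), 0.5)       # |0|*3 + |4| over 8
  expect_equal(gii(mk(rep(3, 4))), 0)             # homogeneous
  m <- mk(c(1, 2, 5, 8))
  expect_equal(gii(m), gii(structure(2 * m, class = class(m))))  # scale-invariant
  expect_error(gii(mk(c(-2, -2, 1, 1))), class = "eitcpr_undefined")
})

test_that("EELI/VT falls by the injected drift during compressions", {
  sim <- cc_sim(subject_params(noise_sd = 0.3), seed = 6)
  rec <- remove_cc_artifact(sim$recording)
  g <- global_signal(rec)
  br <- segment_breaths(g, FS_EIT)
  # baseline breaths must end before the compressions start
  base <- br[(br$end_exp_idx - 1) / FS_EIT <= 30, ]
  ref <- stats::median(base$eeli_au)
  cc_breaths <- br[br$onset_s >= 30 & br$onset_s < 90, ]
  e <- eeli_over_vt(g, cc_breaths, reference = ref)
  expect_equal(e, sim$truth$eeli_over_vt_cc, tolerance = 0.1)
  # baseline epoch referenced to itself sits near zero
  e0 <- eeli_over_vt(g, base, reference = ref)
  expect_lt(abs(e0), 0.1)
  expect_lt(e, e0)   # drift makes the after value more negative
  expect_warning(eeli_over_vt(g, cc_breaths[1:2, ], reference = ref),
                 class = "eitcpr_short_epoch")
})

test_that("index set aggregation recovers per-epoch truth including VT scaling", {
  # epoch boundary placed mid-expiration (33 s) so no cycle onset sits on it
  segs <- data.frame(label = c("flat", "tilt35"),
                     angle_start = c(0, 35), angle_end = c(0, 35),
                     cc = FALSE, measure = TRUE, ramp = FALSE,
                     start_s = c(0, 33), end_s = c(33, 72))
  sp <- small_subject(noise_sd = 0,
                      inclination_effect = c("0" = 1, "35" = 0.5))
  sim <- simulate_eit_recording(sp, cc = compression_settings(),
                                duration_s = 72, seed = 7, segments = segs)
  idx <- compute_index_set(sim$recording, filter = FALSE)
  expect_equal(nrow(idx), 2)
  expect_equal(idx$vt_eit_au[2] / idx$vt_eit_au[1], 0.5, tolerance = 0.05)
  # noiseless recording starts at an onset: 6 cycles begin in [0, 33) and 5
  # in [33, 72) (the last cycle is truncated by the recording edge)
  expect_equal(idx$n_breaths, c(6L, 5L))
})
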
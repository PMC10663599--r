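# Ventilation waveform: normalized cycle in [0, 1]. Linear rise over the
# insufflation, plateau 1 during the pause, exponential decay over the
# expiration rescaled to reach exactly 0 at end-expiration (so amplitude
# recovery is exact by construction on noiseless data).
resp_waveform <- function(t, vent, tau_exp = 0.8) {
  tcyc <- 60 / vent$rate_per_min
  ph <- t %% tcyc
  ti <- vent$t_insufflation_s
  tp <- vent$t_pause_s
  te <- vent$t_expiration_s
  w <- numeric(length(ph))
  i1 <- ph < ti
  i2 <- !i1 & ph < ti + tp
  i3 <- !(i1 | i2)
  w[i1] <- ph[i1] / ti
  w[i2] <- 1
  e0 <- exp(-te / tau_exp)
  w[i3] <- (exp(-(ph[i3] - ti - tp) / tau_exp) - e0) / (1 - e0)
  w
}

# Per-frame EELI drift level: first-order relaxation toward -magnitude inside
# compression windows, level held between and after windows (the impedance
# baseline settles at a new, lower stable value once compressions stop).
drift_level <- function(t, windows, magnitude, tau) {
  lev <- numeric(length(t))
  if (!nrow(windows) || magnitude == 0) return(lev)
  cur <- 0
  prev_end <- -Inf
  for (k in seq_len(nrow(windows))) {
    s <- windows[k, 1]; e <- windows[k, 2]
    lev[t > prev_end & t < s] <- cur
    inw <- t >= s & t <= e
    lev[inw] <- -magnitude + (cur + magnitude) * exp(-(t[inw] - s) / tau)
    cur <- -magnitude + (cur + magnitude) * exp(-(e - s) / tau)
    prev_end <- e
  }
  lev[t > prev_end] <- cur
  lev
}

# Per-frame tidal scaling factor from inclination segments. Angles are
# mapped through the subject's inclination_effect table; ramp segments
# interpolate the factor linearly in time.
inclination_factor <- function(t, segments, effect) {
  f <- rep(1, length(t))
  if (is.null(segments) || !nrow(segments)) return(f)
  eff_at <- function(angle) {
    key <- as.character(angle)
    if (key %in% names(effect)) return(unname(effect[key]))
    # interpolate between tabulated angles for ramp positions
    ang <- as.numeric(names(effect))
    o <- order(ang)
    stats::approx(ang[o], unname(effect[o]), xout = angle, rule = 2)$y
  }
  for (k in seq_len(nrow(segments))) {
    idx <- t >= segments$start_s[k] & t < segments$end_s[k]
    if (!any(idx)) next
    if (isTRUE(segments$ramp[k]) &&
        segments$angle_end[k] != segments$angle_start[k]) {
      frac <- (t[idx] - segments$start_s[k]) /
        (segments$end_s[k] - segments$start_s[k])
      ang <- segments$angle_start[k] +
        frac * (segments$angle_end[k] - segments$angle_start[k])
      f[idx] <- vapply(ang, eff_at, numeric(1))
    } else {
      f[idx] <- eff_at(segments$angle_end[k])
    }
  }
  f
}

#' Simulate an EIT recording with known ground truth
#'
#' Generates a reconstructed frame stream emulating mechanically ventilated
#' lungs under (optional) asynchronous mechanical chest compressions.
#' Per-pixel signal model, all components additive:
#'
#' * tidal component: the pixel's amplitude times a normalized ventilation
#'   waveform (linear rise over the insufflation, plateau over the pause,
#'   exponential decay over the expiration), time-shifted per pixel by its
#'   inflation-onset delay and scaled by the inclination factor;
#' * antiphase (pendelluft) pixels use the negated waveform;
#' * compression artifact: fundamental plus second harmonic at the device
#'   rate inside compression windows, weighted per pixel by its relative
#'   tidal amplitude;
#' * end-expiratory drift: first-order fall during compression windows,
#'   distributed over in-phase pixels proportionally to amplitude;
#' * white Gaussian pixel noise.
#'
#' @param subject A [subject_params()] object.
#' @param vent A [ventilator_settings()] object.
#' @param cc A [compression_settings()] object (its `windows` place the
#'   compression bouts; leave empty for no compressions).
#' @param fs_hz Frame rate (Hz); must exceed twice the compression frequency.
#' @param duration_s Recording length (s); at least one ventilatory cycle.
#' @param seed Integer seed for the pixel noise.
#' @param segments Optional inclination segment data frame (see
#'   [protocol_segments()]); default is a single flat segment.
#' @param tau_exp Expiratory time constant of the impedance waveform (s).
#' @param sequence,subject_id Labels stored in the annotations.
#' @return A list with elements `recording` (an [eit_recording()]) and
#'   `truth` (class `eit_ground_truth`): the injected parameter values and
#'   derived noiseless quantities (net global tidal amplitude per
#'   measurement segment, pendelluft %VT_EIT, anterior/posterior ratio,
#'   global inhomogeneity index, per-pixel regional-delay map and its SD,
#'   EELI drift, breath onset times, and the clean artifact-free global
#'   trace).
#' @examples
#' sim <- simulate_eit_recording(subject_params(grid_dims = c(16, 16)),
#'                               duration_s = 30, seed = 1)
#' sim$recording
#' @export
simulate_eit_recording <- function(subject = subject_params(),
                                   vent = ventilator_settings(),
                                   cc = compression_settings(),
                                   fs_hz = 13.58,
                                   duration_s = 120,
                                   seed = 1,
                                   segments = NULL,
                                   tau_exp = 0.8,
                                   sequence = NULL,
                                   subject_id = NULL) {
  if (!inherits(subject, "subject_params")) abort_invalid("subject must be subject_params()")
  cc_hz <- cc$rate_per_min / 60
  if (nrow(cc$windows) && fs_hz <= 2 * cc_hz) {
    abort_invalid("frame rate %.2f Hz cannot represent the %.2f Hz compression artifact (aliasing)",
                  fs_hz, cc_hz)
  }
  tcyc <- 60 / vent$rate_per_min
  if (duration_s < tcyc) abort_invalid("duration must cover at least one ventilatory cycle")
  if (!any(subject$mask)) abort_invalid("lung mask is empty")
  if (nrow(cc$windows) && any(cc$windows[, 2] > duration_s + 1e-9)) {
    abort_invalid("compression windows extend beyond the recording duration")
  }

  rows <- subject$grid_dims[1]; cols <- subject$grid_dims[2]
  nT <- floor(duration_s * fs_hz) + 1L
  t <- (seq_len(nT) - 1) / fs_hz
  mask <- subject$mask
  pend <- subject$pendelluft_pixels
  amp <- subject$tidal_amplitude_map
  npx <- sum(mask)
  px <- which(mask)                      # column-major pixel index
  amp_px <- amp[px]
  pend_px <- pend[px]
  delay_px <- subject$delay_map[px]

  factor_t <- inclination_factor(t, segments, subject$inclination_effect)

  # Tidal component, grouping pixels by unique onset delay (pure time shift
  # of the periodic waveform, so zero-phase filtering preserves inter-pixel
  # timing differences exactly).
  S <- matrix(0, nT, npx)
  for (d in unique(delay_px)) {
    w <- resp_waveform(t - d * vent$t_insufflation_s, vent, tau_exp) * factor_t
    j <- which(delay_px == d & !pend_px)
    if (length(j)) S[, j] <- w %o% amp_px[j]
    j <- which(delay_px == d & pend_px)
    if (length(j)) S[, j] <- (-w) %o% amp_px[j]
  }

  # Compression artifact: fundamental + 2nd harmonic, inside windows only,
  # per-pixel weight proportional to relative tidal amplitude.
  if (nrow(cc$windows) && cc$depth_scale != 0) {
    art <- numeric(nT)
    for (k in seq_len(nrow(cc$windows))) {
      inw <- t >= cc$windows[k, 1] & t <= cc$windows[k, 2]
      art[inw] <- sin(2 * pi * cc_hz * t[inw]) +
        0.3 * sin(4 * pi * cc_hz * t[inw])
    }
    S <- S + (cc$depth_scale * art) %o% amp_px
  }

  # End-expiratory drift during compression windows, over in-phase pixels.
  drift <- drift_level(t, cc$windows, subject$eeli_drift[1], subject$eeli_drift[2])
  pos_share <- ifelse(pend_px, 0, amp_px / sum(amp_px[!pend_px]))
  S <- S + drift %o% pos_share

  truth_global <- rowSums(S)             # clean global trace (pre-noise)

  if (subject$noise_sd > 0) {
    S <- S + with_seed(seed, matrix(stats::rnorm(nT * npx, sd = subject$noise_sd), nT, npx))
  }

  fr <- matrix(0, nT, rows * cols)
  fr[, px] <- S
  frames <- array(fr, dim = c(nT, rows, cols))

  annotations <- list(cc_windows = cc$windows,
                      segments = segments,
                      sequence = sequence,
                      subject = subject_id)
  rec <- eit_recording(frames, fs_hz, mask, annotations)

  signed <- subject_signed_map(subject)
  b <- floor(rows / 2)
  ant <- sum(signed[seq_len(b), ])
  post <- sum(signed[seq(b + 1, rows), ])
  v <- signed[mask]
  net_vt <- subject_vt_truth(subject)
  p_frac <- sum(amp[pend]) / net_vt
  ti <- vent$t_insufflation_s
  t_infl <- vent$t_insufflation_s + vent$t_pause_s
  rvd_px <- 100 * (delay_px * ti + 0.4 * ti) / t_infl
  rvd_px <- rvd_px[!pend_px]
  seg_truth <- NULL
  if (!is.null(segments)) {
    seg_truth <- segments[segments$measure, c("label", "angle_end", "start_s", "end_s"), drop = FALSE]
    if (nrow(seg_truth)) {
      eff <- subject$inclination_effect
      ang <- as.numeric(names(eff))
      seg_truth$vt_factor <- stats::approx(ang, unname(eff),
                                           xout = seg_truth$angle_end,
                                           rule = 2)$y
      seg_truth$vt_eit_au <- net_vt * seg_truth$vt_factor
    }
  }

  truth <- structure(list(
    vt_eit_au = net_vt,
    pendelluft_pct_vt = -100 * p_frac,
    ap_ratio = ant / post,
    gii = sum(abs(v - stats::median(v))) / sum(v),
    rvd_pct = rvd_px,
    sdrvd_pct = stats::sd(rvd_px) * sqrt((length(rvd_px) - 1) / length(rvd_px)),
    eeli_drift_au = subject$eeli_drift[1],
    eeli_drift_tau_s = subject$eeli_drift[2],
    eeli_over_vt_cc = -subject$eeli_drift[1] / net_vt,
    inclination_effect = subject$inclination_effect,
    segments = seg_truth,
    onsets_s = seq(0, duration_s - tcyc + 1e-9, by = tcyc),
    cc_windows = cc$windows,
    global_clean = truth_global,
    signed_map = signed,
    noise_sd = subject$noise_sd,
    seed = seed
  ), class = "eit_ground_truth")

  list(recording = rec, truth = truth)
}

#' @export
print.eit_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: VT %.1f a.u., pendelluft %.1f %%VT, A/P %.2f, GII %.3f, SDRVD %.2f %%\n",
              x$vt_eit_au, x$pendelluft_pct_vt, x$ap_ratio, x$gii, x$sdrvd_pct))
  cat(sprintf("  EELI drift %.1f a.u. (tau %.1f s) -> EELI/VT %.2f during compressions\n",
              x$eeli_drift_au, x$eeli_drift_tau_s, x$eeli_over_vt_cc))
  invisible(x)
}
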
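# trapezoidal quadrature on a uniform-or-not grid
trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

#' Segment ventilator breaths on the flow trace
#'
#' Inspiration is where flow exceeds a threshold (a fraction of peak flow);
#' the end-inspiratory pause is the following near-zero-flow stretch before
#' expiratory (negative) flow. Breaths without a detectable pause are
#' flagged (`has_pause = FALSE`) and skipped by the compliance computation;
#' breaths overlapping chest-compression windows are flagged excluded, as
#' compliance is only meaningful in compression-free time.
#'
#' @param sig A [signal_recording()].
#' @param flow_threshold_frac Inspiration threshold as a fraction of peak
#'   inspiratory flow.
#' @param min_pause_s Minimum pause duration to accept a plateau (s).
#' @param cc_windows Optional two-column matrix of compression windows (s).
#' @return Data frame with one row per breath: sample indexes of
#'   inspiration start/end, pause end, expiration end, plus `has_pause`
#'   and `excluded` flags.
#' @export
segment_vent_breaths <- function(sig, flow_threshold_frac = 0.05,
                                 min_pause_s = 0.3, cc_windows = NULL) {
  stopifnot(inherits(sig, "signal_recording"))
  f <- sig$flow_L_s
  if (!length(f)) abort_invalid("flow trace is empty")
  # light running-median smoothing (~125 ms) so measurement noise does not
  # fragment the threshold crossings; pressures are left untouched
  ks <- min(length(f) - (length(f) + 1L) %% 2L, 25L)
  fsm <- if (ks >= 3) stats::runmed(f, ks) else f
  thr <- flow_threshold_frac * max(fsm)
  if (!is.finite(thr) || thr <= 0) abort_invalid("no inspiratory flow found")
  insp <- fsm > thr
  r <- rle(insp)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # a real inspiration is sustained and reaches near-peak flow; short or
  # low excursions are noise
  keep <- (runs[, 2] - runs[, 1] + 1L >= max(3L, round(0.05 * sig$fs_hz))) &
    vapply(seq_len(nrow(runs)),
           function(i) max(fsm[runs[i, 1]:runs[i, 2]]) >= 0.5 * max(fsm),
           logical(1))
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) abort_invalid("no inspiratory flow found")
  n <- length(f)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs[i, 1]; i1 <- runs[i, 2]
    nxt <- if (i < nrow(runs)) runs[i + 1, 1] - 1L else n
    # pause: from end of inspiratory flow until expiratory flow begins
    j <- i1 + 1L
    while (j <= nxt && fsm[j] > -thr) j <- j + 1L
    pause_end <- j - 1L
    has_pause <- (pause_end - i1) / sig$fs_hz >= min_pause_s
    data.frame(insp_start_idx = i0, insp_end_idx = i1,
               pause_end_idx = pause_end, exp_end_idx = nxt,
               has_pause = has_pause, excluded = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(cc_windows) && nrow(cc_windows)) {
    t0 <- sig$time_s[out$insp_start_idx]
    t1 <- sig$time_s[out$exp_end_idx]
    for (k in seq_len(nrow(cc_windows))) {
      out$excluded <- out$excluded |
        (t0 < cc_windows[k, 2] & t1 > cc_windows[k, 1])
    }
  }
  if (!any(out$has_pause)) {
    warn_eitcpr("no end-inspiratory pause detected; compliances will not be computed",
                class = "eitcpr_no_pause")
  }
  out
}

#' Breath-by-breath lung and chest-wall compliance
#'
#' For each valid breath: tidal volume as the integral of inspiratory flow;
#' plateau pressures averaged over the final third of the end-inspiratory
#' pause; end-expiratory pressures averaged over the final 200 ms before
#' inspiration. Then
#' `C_rs = VT / (Paw_plat - Paw_ee)`,
#' `C_cw = VT / (Pes_plat - Pes_ee)` and
#' `C_lung = VT / ((Paw - Pes)_plat - (Paw - Pes)_ee)`
#' (transpulmonary pressure partitioning via esophageal manometry). Breaths
#' without a pause, excluded breaths, or breaths with non-positive driving
#' pressure yield `NA` compliances and a `valid = FALSE` flag. Without an
#' esophageal trace only `C_rs` is computed.
#'
#' @param sig A [signal_recording()].
#' @param breaths Output of [segment_vent_breaths()]; computed if omitted.
#' @param ee_window_s End-expiratory sampling window (s).
#' @param ... Passed to [segment_vent_breaths()].
#' @return Data frame of class `breath_mechanics`: per breath `vt_ml`,
#'   plateau and end-expiratory pressures, `c_rs_ml_cmH2O`,
#'   `c_lung_ml_cmH2O`, `c_cw_ml_cmH2O`, `valid`.
#' @export
compliance <- function(sig, breaths = NULL, ee_window_s = 0.2, ...) {
  stopifnot(inherits(sig, "signal_recording"))
  if (is.null(breaths)) breaths <- segment_vent_breaths(sig, ...)
  has_pes <- !is.null(sig$pes_cmH2O)
  nee <- max(1L, round(ee_window_s * sig$fs_hz))
  rows <- lapply(seq_len(nrow(breaths)), function(i) {
    b <- breaths[i, ]
    out <- data.frame(vt_ml = NA_real_, paw_plateau_cmH2O = NA_real_,
                      pes_plateau_cmH2O = NA_real_, paw_ee_cmH2O = NA_real_,
                      pes_ee_cmH2O = NA_real_, c_rs_ml_cmH2O = NA_real_,
                      c_lung_ml_cmH2O = NA_real_, c_cw_ml_cmH2O = NA_real_,
                      valid = FALSE)
    # include one flanking sample on each side so the trapezoid captures the
    # flow transitions at the window edges
    win <- max(1L, b$insp_start_idx - 1L):min(length(sig$flow_L_s), b$insp_end_idx + 1L)
    out$vt_ml <- trapz(sig$time_s[win], sig$flow_L_s[win]) * 1000
    if (!b$has_pause || b$excluded) return(out)
    # plateau: final third of the pause
    p0 <- b$insp_end_idx + 1L; p1 <- b$pause_end_idx
    pl <- seq(p0 + floor(2 * (p1 - p0) / 3), p1)
    # end-expiration: final window before this inspiration
    ee <- seq(max(1L, b$insp_start_idx - nee), b$insp_start_idx - 1L)
    if (!length(ee) || ee[1] < 1) return(out)
    out$paw_plateau_cmH2O <- mean(sig$paw_cmH2O[pl])
    out$paw_ee_cmH2O <- mean(sig$paw_cmH2O[ee])
    dp_rs <- out$paw_plateau_cmH2O - out$paw_ee_cmH2O
    if (is.na(dp_rs) || dp_rs <= 0) return(out)
    out$c_rs_ml_cmH2O <- out$vt_ml / dp_rs
    if (has_pes) {
      out$pes_plateau_cmH2O <- mean(sig$pes_cmH2O[pl])
      out$pes_ee_cmH2O <- mean(sig$pes_cmH2O[ee])
      dp_cw <- out$pes_plateau_cmH2O - out$pes_ee_cmH2O
      dp_l <- dp_rs - dp_cw
      if (dp_cw > 0) out$c_cw_ml_cmH2O <- out$vt_ml / dp_cw
      if (dp_l > 0) out$c_lung_ml_cmH2O <- out$vt_ml / dp_l
    }
    out$valid <- TRUE
    out
  })
  out <- cbind(breaths, do.call(rbind, rows))
  class(out) <- c("breath_mechanics", "data.frame")
  out
}

#' Before/after compression change in compliance
#'
#' Per-subject breath means are taken on each side, and the
#' after-minus-before change is estimated with a random-intercept model
#' (subject as the random effect) via [paired_cc_contrast()]. A positive
#' change means compliance is greater after the compressions.
#'
#' @param before,after Data frames with a `subject` column and the outcome
#'   column (per-breath values).
#' @param outcome Column name, e.g. `"c_lung_ml_cmH2O"`.
#' @return A `cc_contrast` object: estimate, 95% CI, p-value.
#' @export
compliance_change <- function(before, after, outcome = "c_lung_ml_cmH2O") {
  agg <- function(d) {
    if (!nrow(d)) abort_invalid("empty breath table for one side")
    v <- tapply(d[[outcome]], d$subject, mean, na.rm = TRUE)
    data.frame(subject = names(v), value = as.numeric(v))
  }
  bm <- agg(before); am <- agg(after)
  common <- intersect(bm$subject, am$subject)
  common <- common[!is.na(bm$value[match(common, bm$subject)]) &
                     !is.na(am$value[match(common, am$subject)])]
  if (!length(common)) abort_invalid("no subject has valid breaths on both sides")
  paired_cc_contrast(bm$value[match(common, bm$subject)],
                     am$value[match(common, am$subject)],
                     common)
}
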
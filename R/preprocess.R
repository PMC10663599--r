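#' Global ventilation signal
#'
#' Sum of the impedance signal over all lung-mask pixels, per frame. This is
#' the trace on which breaths are defined: its minima mark inspiration
#' onsets and its maxima end-inspiration.
#'
#' @param rec An [eit_recording()], or a `time x rows x cols` array.
#' @param mask Lung mask (required when `rec` is a bare array).
#' @return Numeric vector, one value per frame (a.u.).
#' @export
global_signal <- function(rec, mask = NULL) {
  if (inherits(rec, "eit_recording")) {
    frames <- rec$frames
    if (is.null(mask)) mask <- rec$mask
  } else {
    frames <- rec
  }
  if (is.null(mask) || !any(mask)) abort_invalid("lung mask is empty")
  d <- dim(frames)
  if (!identical(dim(mask), d[2:3])) abort_invalid("mask dimensions must match frames")
  m <- matrix(frames, nrow = d[1])
  rowSums(m[, which(mask), drop = FALSE])
}

# default low-pass cutoff: geometric mean of the respiratory 3rd harmonic
# and the compression fundamental.
default_cutoff_hz <- function(resp_rate_per_min, cc_rate_per_min) {
  sqrt((3 * resp_rate_per_min / 60) * (cc_rate_per_min / 60))
}

# Zero-phase Butterworth low-pass with even-reflection end padding to
# suppress edge transients; returns a vector of the input length.
zero_phase_lowpass <- function(x, fs_hz, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 * fs_hz / cutoff_hz))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + n)]
}

#' Remove the chest-compression artifact
#'
#' Zero-phase low-pass filtering that separates the respiratory signal
#' (fundamental 0.167 Hz at 10 breaths/min) from the mechanical compression
#' artifact (fundamental 1.7 Hz at 102/min). The default cutoff is the
#' geometric mean of the respiratory third harmonic and the compression
#' fundamental (0.92 Hz for the default rates). The order-4 Butterworth
#' filter is applied forward and backward, so breath timing is unbiased and
#' the effective attenuation at the compression fundamental exceeds 40 dB
#' while the respiratory fundamental is passed essentially unchanged.
#'
#' When given a frame array or recording, the identical kernel is applied to
#' every pixel time series, so filtering commutes with the global sum.
#'
#' @param x Numeric vector (global signal), 3-D frame array, or
#'   [eit_recording()].
#' @param fs_hz Sampling rate (Hz); taken from the recording if omitted.
#' @param resp_rate_per_min Respiratory rate used to set the cutoff.
#' @param cc_rate_per_min Compression rate used to set the cutoff.
#' @param cutoff_hz Explicit cutoff override (Hz).
#' @param order Butterworth order (applied twice).
#' @return Filtered object of the same shape/class as `x`.
#' @export
remove_cc_artifact <- function(x, fs_hz = NULL,
                               resp_rate_per_min = 10,
                               cc_rate_per_min = 102,
                               cutoff_hz = NULL, order = 4) {
  if (inherits(x, "eit_recording")) {
    out <- x
    out$frames <- remove_cc_artifact(x$frames, x$fs_hz,
                                     resp_rate_per_min, cc_rate_per_min,
                                     cutoff_hz, order)
    return(out)
  }
  if (is.null(fs_hz)) abort_invalid("fs_hz is required for vector/array input")
  resp_hz <- resp_rate_per_min / 60
  cc_hz <- cc_rate_per_min / 60
  if (cc_hz >= fs_hz / 2) {
    abort_infeasible_filter("compression rate %.2f Hz is at or above Nyquist (%.2f Hz)",
                            cc_hz, fs_hz / 2)
  }
  if (3 * resp_hz >= cc_hz) {
    abort_infeasible_filter(
      "respiratory harmonics (3rd at %.2f Hz) reach the compression fundamental (%.2f Hz); bands overlap",
      3 * resp_hz, cc_hz)
  }
  if (is.null(cutoff_hz)) cutoff_hz <- default_cutoff_hz(resp_rate_per_min, cc_rate_per_min)
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort_infeasible_filter("cutoff %.2f Hz outside (0, Nyquist)", cutoff_hz)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    keep <- which(colSums(abs(m)) > 0)
    for (j in keep) m[, j] <- zero_phase_lowpass(m[, j], fs_hz, cutoff_hz, order)
    return(array(m, dim = d))
  }
  zero_phase_lowpass(as.numeric(x), fs_hz, cutoff_hz, order)
}

#' Detect chest-compression windows from band power
#'
#' Locates time windows whose short-time spectral power in the compression
#' band (default 1.4-2.0 Hz) exceeds an adaptive threshold
#' (median + k * MAD of the short-time powers, k = 6 by default). Window
#' boundaries are then refined to the half-power crossing of each detected
#' bout, and bouts separated by less than `merge_gap_s` are merged.
#'
#' @param x Global impedance signal (unfiltered) or an [eit_recording()].
#' @param fs_hz Sampling rate (Hz).
#' @param cc_band_hz Length-2 band (Hz) containing the compression
#'   fundamental; must lie below Nyquist.
#' @param window_s,hop_s Short-time analysis window length and hop (s).
#' @param k MAD multiplier of the adaptive threshold.
#' @param min_band_fraction Candidate windows must also place at least this
#'   fraction of their total power in the compression band (respiratory
#'   harmonic leakage never does; the mechanical artifact dominates).
#' @param merge_gap_s Bouts closer than this are merged (s).
#' @return Two-column matrix of `(start_s, end_s)`; zero rows when no
#'   compressions are found.
#' @export
detect_cc_windows <- function(x, fs_hz = NULL, cc_band_hz = c(1.4, 2.0),
                              window_s = 2, hop_s = 0.25, k = 6,
                              min_band_fraction = 0.1,
                              merge_gap_s = 2) {
  if (inherits(x, "eit_recording")) {
    fs_hz <- x$fs_hz
    x <- global_signal(x)
  }
  if (is.null(fs_hz)) abort_invalid("fs_hz is required")
  if (cc_band_hz[2] >= fs_hz / 2) abort_invalid("cc band must lie below Nyquist")
  n <- length(x)
  wlen <- round(window_s * fs_hz)
  hop <- max(1L, round(hop_s * fs_hz))
  if (n < wlen) abort_invalid("signal shorter than the analysis window")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  centers <- ((starts - 1) + (wlen - 1) / 2) / fs_hz
  freqs <- (seq_len(wlen) - 1) * fs_hz / wlen
  inband <- freqs >= cc_band_hz[1] & freqs <= cc_band_hz[2]
  pw <- numeric(length(starts))
  frac <- numeric(length(starts))
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + wlen - 1L)]
    sp <- Mod(stats::fft(seg - mean(seg)))^2
    pw[w] <- sum(sp[inband])
    tot <- sum(sp)
    frac[w] <- if (tot > 0) 2 * pw[w] / tot else 0  # both spectrum halves
  }
  # Adaptive threshold from the quiescent power distribution. Compressions
  # may cover most of the recording, so the quiescent level is estimated
  # from the lower half of the short-time powers; a detected bout must also
  # clearly dominate that level (the artifact is orders of magnitude above
  # respiratory harmonic leakage in the band).
  quies <- pw[pw <= stats::median(pw)]
  base <- stats::median(quies)
  thr <- base + k * stats::mad(quies)
  above <- pw > thr & pw > 10 * base & frac >= min_band_fraction & pw > 0
  if (!any(above)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s"))))
  }
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- cbind(starts_i[r$values], ends_i[r$values])
  # refine each run boundary to the half-power crossing
  refine <- function(i0, i1) {
    level <- stats::median(pw[i0:i1])
    half <- level / 2
    lo <- i0
    while (lo > 1 && pw[lo - 1] > half) lo <- lo - 1L
    hi <- i1
    while (hi < length(pw) && pw[hi + 1] > half) hi <- hi + 1L
    cross_t <- function(a, b) {  # linear interpolation of crossing between hops
      if (a < 1 || b > length(pw) || pw[a] == pw[b]) return(centers[max(a, 1)])
      centers[a] + (half - pw[a]) / (pw[b] - pw[a]) * (centers[b] - centers[a])
    }
    c(if (lo > 1) cross_t(lo - 1L, lo) else centers[lo],
      if (hi < length(pw)) cross_t(hi + 1L, hi) else centers[hi])
  }
  wins <- t(apply(runs, 1, function(rw) refine(rw[1], rw[2])))
  # merge close bouts
  if (nrow(wins) > 1) {
    merged <- wins[1, , drop = FALSE]
    for (i in 2:nrow(wins)) {
      if (wins[i, 1] - merged[nrow(merged), 2] < merge_gap_s) {
        merged[nrow(merged), 2] <- wins[i, 2]
      } else merged <- rbind(merged, wins[i, ])
    }
    wins <- merged
  }
  wins[, 1] <- pmax(wins[, 1], 0)
  wins[, 2] <- pmin(wins[, 2], (n - 1) / fs_hz)
  colnames(wins) <- c("start_s", "end_s")
  wins
}

# All local extrema of x with plateau handling: zero differences inherit the
# following non-zero sign, so a flat top is marked at its first sample.
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(data.frame(idx = integer(0), type = character(0)))
  # backward-fill zeros with the next non-zero sign
  filled <- rev(cummax_sign(rev(s)))
  chg <- which(filled[-1] != filled[-length(filled)])
  idx <- chg + 1L
  type <- ifelse(filled[chg] > 0, "max", "min")
  data.frame(idx = idx, type = type, stringsAsFactors = FALSE)
}

# carry the last non-zero value forward (helper for plateau sign filling)
cummax_sign <- function(s) {
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  s
}

#' Segment breaths on the filtered global signal
#'
#' Inspiration onsets are local minima of the global impedance signal and
#' end-inspiration its maxima. Candidate extrema are forced to alternate
#' (of consecutive same-type extrema the more extreme is kept) and swings
#' smaller than `prominence_frac` of the median cycle amplitude are pruned,
#' so residual compression artifact is not counted as breaths. Because the
#' end-inspiratory pause makes the signal maximum a plateau, end-inspiration
#' is taken as the last sample within `plateau_tol` of the cycle maximum:
#' the ventilatory hold belongs to inspiration. Each breath spans onset to
#' next onset; partial cycles at the edges are discarded.
#'
#' @param x Filtered global signal (numeric vector).
#' @param fs_hz Sampling rate (Hz).
#' @param prominence_frac Minimum swing as a fraction of the cycle amplitude
#'   (estimated robustly as the 5th-to-95th percentile span of the signal
#'   after removing a running-median trend).
#' @param plateau_tol End-inspiration plateau tolerance as a fraction of the
#'   cycle amplitude: end-inspiration is the last sample, contiguous with
#'   the cycle maximum, whose value is within this band. With a
#'   constant-flow insufflation followed by a hold this places
#'   end-inspiration at the end of the hold.
#' @return A data frame of class `breath_table` with columns `onset_idx`,
#'   `max_idx` (cycle maximum), `end_insp_idx` (end of the inspiratory
#'   hold), `end_exp_idx` (1-based frame indexes), `onset_s`, `vt_eit_au`
#'   (cycle maximum minus the onset value) and `eeli_au` (cycle minimum).
#'   Zero rows when no full cycle is present.
#' @export
segment_breaths <- function(x, fs_hz, prominence_frac = 0.1,
                            plateau_tol = 0.10) {
  x <- as.numeric(x)
  ex <- local_extrema(x)
  empty <- data.frame(onset_idx = integer(0), max_idx = integer(0),
                      end_insp_idx = integer(0),
                      end_exp_idx = integer(0), onset_s = numeric(0),
                      vt_eit_au = numeric(0), eeli_au = numeric(0))
  class(empty) <- c("breath_table", "data.frame")
  if (nrow(ex) < 3) return(empty)

  collapse_alternate <- function(ex) {
    out_idx <- integer(0); out_type <- character(0)
    for (r in seq_len(nrow(ex))) {
      if (length(out_type) && ex$type[r] == out_type[length(out_type)]) {
        k <- length(out_idx)
        better <- if (ex$type[r] == "max") x[ex$idx[r]] > x[out_idx[k]]
                  else x[ex$idx[r]] < x[out_idx[k]]
        if (better) out_idx[k] <- ex$idx[r]
      } else {
        out_idx <- c(out_idx, ex$idx[r])
        out_type <- c(out_type, ex$type[r])
      }
    }
    data.frame(idx = out_idx, type = out_type, stringsAsFactors = FALSE)
  }
  ex <- collapse_alternate(ex)

  # Robust cycle-amplitude estimate: percentile span of the detrended signal
  # (a running median over ~2 cycles absorbs slow baseline drift so the
  # amplitude is not inflated by, e.g., the compression-induced EELI fall).
  win <- max(3L, round(12 * fs_hz))
  win <- win + (win + 1L) %% 2L   # odd
  trend <- if (length(x) > win) stats::runmed(x, win) else rep(stats::median(x), length(x))
  amp_est <- diff(stats::quantile(x - trend, c(0.05, 0.95), names = FALSE))
  thr <- prominence_frac * amp_est

  # prune swings below threshold, smallest first, re-collapsing after each
  repeat {
    if (nrow(ex) < 3) return(empty)
    swings <- abs(diff(x[ex$idx]))
    small <- which(swings < thr)
    if (!length(small)) break
    j <- small[which.min(swings[small])]
    ex <- collapse_alternate(ex[-c(j, j + 1L), , drop = FALSE])
  }

  mins <- which(ex$type == "min")
  segs <- vector("list", length(mins))
  for (k in seq_along(mins)) {
    m <- mins[k]
    if (m + 2L > nrow(ex)) break
    if (ex$type[m + 1L] != "max" || ex$type[m + 2L] != "min") {
      abort_invalid("non-alternating extrema after prominence filtering")
    }
    onset <- ex$idx[m]
    nxt <- ex$idx[m + 2L]
    cyc <- x[onset:nxt]
    cmax <- max(cyc)
    tol <- plateau_tol * (cmax - min(cyc))
    # last sample within the plateau band, contiguous with the maximum
    near <- cyc >= cmax - tol
    j <- which.max(cyc)
    while (j < length(cyc) && near[j + 1L]) j <- j + 1L
    segs[[k]] <- data.frame(
      onset_idx = onset, max_idx = onset - 1L + which.max(cyc),
      end_insp_idx = onset - 1L + j, end_exp_idx = nxt,
      onset_s = (onset - 1) / fs_hz,
      vt_eit_au = cmax - x[onset],
      eeli_au = min(cyc))
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  class(out) <- c("breath_table", "data.frame")
  out
}

#' Functional lung mask from tidal variation
#'
#' Standard functional-EIT practice for real recordings without an anatomic
#' mask: pixels whose median per-breath tidal variation exceeds a fraction
#' of the maximal pixel tidal variation in a reference epoch.
#'
#' @param frames Filtered frame array.
#' @param breaths A `breath_table` of reference breaths.
#' @param threshold Fraction of the maximal pixel tidal variation.
#' @return Logical mask matrix.
#' @export
functional_mask <- function(frames, breaths, threshold = 0.2) {
  if (!nrow(breaths)) abort_invalid("no reference breaths supplied")
  d <- dim(frames)
  m <- matrix(frames, nrow = d[1])
  dif <- vapply(seq_len(nrow(breaths)), function(i) {
    abs(m[breaths$end_insp_idx[i], ] - m[breaths$onset_idx[i], ])
  }, numeric(ncol(m)))
  med <- apply(dif, 1, stats::median)
  matrix(med >= threshold * max(med), d[2], d[3])
}
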
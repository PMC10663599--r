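#' Breath-wise tidal impedance change
#'
#' The rise of the global impedance signal over one inspiration: cycle
#' maximum minus the value at inspiration onset (for pause-free signals the
#' maximum is the end-inspiration sample). Non-negative by construction of
#' the breath table.
#'
#' @param x Filtered global signal.
#' @param breath One row of a [segment_breaths()] table.
#' @return Tidal impedance change (a.u.).
#' @export
vt_eit <- function(x, breath) {
  if (breath$end_exp_idx > length(x) || breath$onset_idx < 1) {
    abort_invalid("breath indexes outside the signal")
  }
  max(x[breath$onset_idx:breath$end_exp_idx]) - x[breath$onset_idx]
}

#' Per-pixel tidal impedance map for one breath
#'
#' Signed per-pixel impedance change between the global breath's onset and
#' cycle-maximum frames. Using the global breath's frames (not per-pixel
#' extrema) keeps negative values interpretable as antiphase (pendelluft)
#' behaviour and makes the map sum exactly to the global tidal change
#' (`vt_eit_au`) over the same frames. A per-pixel-extrema variant is
#' available for sensitivity analysis.
#'
#' @param frames Frame array filtered with the same kernel as the global
#'   signal.
#' @param breath One row of a breath table.
#' @param mask Logical lung mask.
#' @param per_pixel_extrema If `TRUE`, use each pixel's own min/max within
#'   the breath (all values non-negative; conservation no longer holds).
#' @return A `pixel_map`: matrix with `NA` outside the mask, the breath row
#'   stored as attribute `breath`.
#' @export
pixel_tidal_map <- function(frames, breath, mask, per_pixel_extrema = FALSE) {
  d <- dim(frames)
  if (!identical(dim(mask), d[2:3])) abort_invalid("mask dimensions must match frames")
  if (breath$end_insp_idx > d[1]) abort_invalid("breath indexes outside the frame array")
  m <- matrix(frames, nrow = d[1])
  if (per_pixel_extrema) {
    win <- breath$onset_idx:breath$end_exp_idx
    vals <- apply(m[win, , drop = FALSE], 2, function(y) max(y) - min(y))
  } else {
    top <- if ("max_idx" %in% names(breath)) breath$max_idx else breath$end_insp_idx
    vals <- m[top, ] - m[breath$onset_idx, ]
  }
  out <- matrix(vals, d[2], d[3])
  out[!mask] <- NA_real_
  structure(out, breath = breath, class = c("pixel_map", "matrix", "array"))
}

#' Anterior-to-posterior ventilation ratio
#'
#' Ratio of the summed tidal impedance change in the anterior half of the
#' grid to that in the posterior half (row 1 is anterior; boundary defaults
#' to the grid midline). A ratio above 1 means ventilation is distributed
#' predominantly ventrally. A non-positive posterior sum makes the ratio
#' undefined; it is reported as `NA` with a warning rather than infinity.
#'
#' @param map A [pixel_tidal_map()].
#' @param boundary_row Last anterior row; default `floor(rows / 2)`.
#' @return The ratio, or `NA_real_` when undefined.
#' @export
ap_ratio <- function(map, boundary_row = NULL) {
  nr <- nrow(map)
  if (is.null(boundary_row)) boundary_row <- floor(nr / 2)
  if (boundary_row < 1 || boundary_row >= nr) abort_invalid("boundary_row outside grid")
  ant <- sum(map[seq_len(boundary_row), ], na.rm = TRUE)
  post <- sum(map[seq(boundary_row + 1, nr), ], na.rm = TRUE)
  if (ant == 0 && post == 0) abort_invalid("anterior and posterior sums are both zero")
  if (post <= 0) {
    warn_eitcpr("posterior tidal sum <= 0; anterior/posterior ratio undefined",
                class = "eitcpr_undefined_ratio")
    return(NA_real_)
  }
  ant / post
}

#' Pendelluft index
#'
#' Summed negative per-pixel tidal impedance changes, normalized to the
#' breath's net tidal change and expressed as a (non-positive) percentage of
#' VT_EIT. Gas moving in antiphase with the ventilator appears as negative
#' pixels, so a value of -10 means antiphase regions carried 10% of the net
#' tidal impedance change. Values below -100 are possible only for
#' pathological maps and are flagged, not clamped.
#'
#' @param map A [pixel_tidal_map()].
#' @return Pendelluft in %VT_EIT (<= 0).
#' @export
pendelluft <- function(map) {
  v <- map[!is.na(map)]
  vt <- sum(v)
  if (vt <= 0) abort_undefined("net tidal change <= 0; pendelluft undefined")
  out <- 100 * sum(v[v < 0]) / vt
  if (out < -100) {
    warn_eitcpr("pendelluft below -100 %%VT_EIT (pathological map)",
                class = "eitcpr_out_of_range")
  }
  out
}

#' Regional ventilation delay map
#'
#' Per pixel, the time taken to reach `threshold` (default 40%) of the
#' pixel's own impedance excursion within the inflation window (breath
#' onset to end-inspiration), expressed as a percentage of the inflation
#' time. The crossing is linearly interpolated between frames. Pixels whose
#' impedance change over the window is not positive (e.g. antiphase pixels)
#' are excluded (`NA`). The standard deviation of the map ([sdrvd()])
#' quantifies inflation heterogeneity.
#'
#' @param frames Frame array (filtered when compressions are present).
#' @param breath One row of a breath table.
#' @param mask Logical lung mask.
#' @param threshold Fraction of the pixel excursion defining the delay.
#' @return An `rvd_map`: matrix of delays in % inflation time (`NA` for
#'   excluded pixels).
#' @export
rvd_map <- function(frames, breath, mask, threshold = 0.40) {
  d <- dim(frames)
  win <- breath$onset_idx:breath$end_insp_idx
  if (length(win) < 3) abort_invalid("inflation window must span at least 3 frames")
  m <- matrix(frames, nrow = d[1])[win, , drop = FALSE]
  nwin <- length(win)
  px <- which(mask)
  vals <- rep(NA_real_, length(px))
  for (k in seq_along(px)) {
    y <- m[, px[k]]
    if (y[nwin] - y[1] <= 0) next
    lo <- min(y); hi <- max(y)
    target <- lo + threshold * (hi - lo)
    i <- which(y >= target)[1]
    tcross <- if (i == 1L) 0 else {
      (i - 2L) + (target - y[i - 1L]) / (y[i] - y[i - 1L])
    }
    vals[k] <- 100 * tcross / (nwin - 1L)
  }
  if (all(is.na(vals))) abort_undefined("all pixels excluded from the delay map")
  out <- matrix(NA_real_, d[2], d[3])
  out[px] <- vals
  structure(out, breath = breath, class = c("rvd_map", "matrix", "array"))
}

#' Standard deviation of the regional ventilation delay
#'
#' Population standard deviation of an [rvd_map()] over included pixels;
#' higher values indicate a more heterogeneous distribution of regional
#' inflation.
#'
#' @param map An `rvd_map`.
#' @return SD in % inflation time.
#' @export
sdrvd <- function(map) {
  v <- map[!is.na(map)]
  if (!length(v)) abort_undefined("no pixels included in the delay map")
  sqrt(mean((v - mean(v))^2))
}

#' Global inhomogeneity index
#'
#' Spatial heterogeneity of the tidal distribution:
#' `sum(|DI - median(DI)|) / sum(DI)` over lung pixels, where `DI` is the
#' pixel tidal impedance change. Zero for perfectly homogeneous
#' ventilation; scale-invariant.
#'
#' @param map A [pixel_tidal_map()].
#' @return The index (unitless, >= 0).
#' @export
gii <- function(map) {
  v <- map[!is.na(map)]
  if (!length(v)) abort_invalid("mask is empty")
  denom <- sum(v)
  if (denom <= 0) abort_undefined("non-positive tidal sum; inhomogeneity index undefined")
  sum(abs(v - stats::median(v))) / denom
}

#' End-expiratory impedance normalized to tidal change
#'
#' Mean over the last `n_last` breaths of (EELI - reference) / VT_EIT,
#' where EELI is the per-breath minimum of the filtered global signal and
#' the reference is the end-expiratory level of a pre-compression baseline
#' epoch. Because impedance is a relative measurement, only this referenced
#' form is meaningful; values fall as end-expiratory lung volume falls.
#'
#' @param x Filtered global signal.
#' @param breaths Breath table for the epoch of interest.
#' @param reference Reference end-expiratory level (a.u.), typically the
#'   median `eeli_au` of baseline breaths.
#' @param n_last Number of final breaths to average (default 3).
#' @return Unitless index (typically <= 0 during compressions).
#' @export
eeli_over_vt <- function(x, breaths, reference = 0, n_last = 3) {
  if (!nrow(breaths)) abort_invalid("no breaths supplied")
  if (nrow(breaths) < n_last) {
    warn_eitcpr("only %d breath(s) available for the last-%d window",
                nrow(breaths), n_last, class = "eitcpr_short_epoch")
  }
  tail_rows <- utils::tail(breaths, n_last)
  mean((tail_rows$eeli_au - reference) / tail_rows$vt_eit_au)
}

#' Compute the full index set per measurement epoch
#'
#' Runs the whole EIT chain on one recording: zero-phase artifact filtering
#' of every pixel, breath segmentation on the global signal, per-breath
#' index computation, and per-epoch aggregation by the median of per-breath
#' values. Epochs default to the recording's annotated measurement segments
#' (the 60-s compression windows at each stable inclination); breaths are
#' attributed to an epoch by their onset time. EELI is referenced to the
#' end-expiratory level of the pre-compression baseline epoch and averaged
#' over the last three breaths of each epoch.
#'
#' @param rec An [eit_recording()].
#' @param epochs Data frame with columns `label`, `inclination`, `start_s`,
#'   `end_s` (default: annotated measurement segments).
#' @param filter Apply compression-artifact filtering (set `FALSE` only for
#'   compression-free noiseless input).
#' @param cc_rate_per_min,resp_rate_per_min,cutoff_hz Filter parameters,
#'   see [remove_cc_artifact()].
#' @param reference_epoch Length-2 numeric `(start_s, end_s)` of the
#'   baseline epoch used as EELI reference; default is the span before the
#'   first compression window (the whole recording when there are none).
#' @return A data frame of class `index_set`, one row per epoch, with the
#'   per-epoch medians of VT_EIT, anterior/posterior ratio, pendelluft,
#'   EELI/VT_EIT, SDRVD, GII, and the breath count.
#' @export
compute_index_set <- function(rec, epochs = NULL, filter = TRUE,
                              cc_rate_per_min = 102, resp_rate_per_min = 10,
                              cutoff_hz = NULL, reference_epoch = NULL) {
  stopifnot(inherits(rec, "eit_recording"))
  dur <- dim(rec$frames)[1] / rec$fs_hz
  if (is.null(epochs)) {
    segs <- rec$annotations$segments
    if (is.null(segs) || !any(segs$measure)) {
      abort_invalid("no epoch annotations present; supply `epochs`")
    }
    msegs <- segs[segs$measure, , drop = FALSE]
    epochs <- data.frame(label = msegs$label,
                         inclination = msegs$angle_end,
                         start_s = msegs$start_s,
                         end_s = pmin(msegs$end_s, msegs$start_s + 60))
  }
  frames <- if (filter) {
    remove_cc_artifact(rec$frames, rec$fs_hz, resp_rate_per_min,
                       cc_rate_per_min, cutoff_hz)
  } else rec$frames
  g <- global_signal(frames, rec$mask)
  breaths <- segment_breaths(g, rec$fs_hz)
  if (!nrow(breaths)) abort_invalid("no breaths detected in the recording")

  if (is.null(reference_epoch)) {
    ccw <- rec$annotations$cc_windows
    reference_epoch <- if (!is.null(ccw) && nrow(ccw)) c(0, ccw[1, 1]) else c(0, dur)
  }
  # reference breaths must lie wholly inside the baseline epoch: a cycle
  # straddling the compression start is already contaminated by the drift
  end_s <- (breaths$end_exp_idx - 1) / rec$fs_hz
  ref_breaths <- breaths[breaths$onset_s >= reference_epoch[1] &
                           end_s <= reference_epoch[2] + 1e-9, , drop = FALSE]
  eeli_ref <- if (nrow(ref_breaths)) stats::median(ref_breaths$eeli_au) else {
    warn_eitcpr("no baseline breaths for the EELI reference; using first-breath EELI",
                class = "eitcpr_no_reference")
    breaths$eeli_au[1]
  }

  rows <- lapply(seq_len(nrow(epochs)), function(e) {
    out <- data.frame(label = epochs$label[e],
                      inclination = epochs$inclination[e],
                      n_breaths = 0L,
                      vt_eit_au = NA_real_, ap_ratio = NA_real_,
                      pendelluft_pct_vt = NA_real_, eeli_over_vt = NA_real_,
                      sdrvd_pct_insp_time = NA_real_, gii = NA_real_,
                      stringsAsFactors = FALSE)
    b <- breaths[breaths$onset_s >= epochs$start_s[e] &
                   breaths$onset_s < epochs$end_s[e], , drop = FALSE]
    if (!nrow(b)) {
      warn_eitcpr("epoch '%s' contains no breaths", epochs$label[e],
                  class = "eitcpr_empty_epoch")
      return(out)
    }
    per <- lapply(seq_len(nrow(b)), function(i) {
      br <- b[i, ]
      pm <- pixel_tidal_map(frames, br, rec$mask)
      rv <- tryCatch(sdrvd(rvd_map(frames, br, rec$mask)),
                     eitcpr_undefined = function(c) NA_real_,
                     eitcpr_invalid_argument = function(c) NA_real_)
      c(vt = br$vt_eit_au,
        ap = suppressWarnings(ap_ratio(pm)),
        pend = tryCatch(pendelluft(pm), eitcpr_undefined = function(c) NA_real_),
        sdrvd = rv,
        gii = tryCatch(gii(pm), eitcpr_undefined = function(c) NA_real_))
    })
    per <- do.call(rbind, per)
    out$n_breaths <- nrow(b)
    out$vt_eit_au <- stats::median(per[, "vt"], na.rm = TRUE)
    out$ap_ratio <- stats::median(per[, "ap"], na.rm = TRUE)
    out$pendelluft_pct_vt <- stats::median(per[, "pend"], na.rm = TRUE)
    out$sdrvd_pct_insp_time <- stats::median(per[, "sdrvd"], na.rm = TRUE)
    out$gii <- stats::median(per[, "gii"], na.rm = TRUE)
    out$eeli_over_vt <- eeli_over_vt(g, b, reference = eeli_ref)
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("index_set", "data.frame")
  out
}
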
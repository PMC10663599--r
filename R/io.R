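# Container formats
# ------------------
# No community standard exists for reconstructed EIT frame streams, so the
# package defines a self-describing pair: a delimited frame matrix (one
# frame per record, pixels flattened row-major, anterior-left origin) plus
# a JSON sidecar (`<path>.json`) carrying a format tag, sampling rate, grid
# dimensions, lung mask and protocol annotations. Pressure/flow traces use
# a delimited table whose column names carry the units, again with a JSON
# sidecar for the ventilator settings.

EIT_FORMAT_TAG <- "eitcpr-frames"
SIG_FORMAT_TAG <- "eitcpr-signals"
FORMAT_VERSION <- 1L

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an EIT recording
#'
#' Lossless round-trip (to ~15 significant digits) of frames, mask,
#' sampling rate and annotations. The frame file holds one frame per
#' record, row-major; the sidecar holds everything else.
#'
#' @param rec An [eit_recording()].
#' @param path Frame-file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_eit` returns `path` invisibly; `read_eit` returns the
#'   recording.
#' @export
write_eit <- function(rec, path) {
  stopifnot(inherits(rec, "eit_recording"))
  d <- dim(rec$frames)
  # row-major flattening: frame t -> as.vector(t(frames[t, , ]))
  m <- matrix(rec$frames, nrow = d[1])
  rowmajor <- as.vector(t(matrix(seq_len(d[2] * d[3]), d[2], d[3])))
  ann <- rec$annotations
  meta <- list(format = EIT_FORMAT_TAG, version = FORMAT_VERSION,
               fs_hz = rec$fs_hz, dims = d[2:3], n_frames = d[1],
               pixel_order = "row-major, row 1 anterior",
               mask = as.integer(rec$mask),
               annotations = list(
                 cc_windows = if (is.null(ann$cc_windows)) NULL else
                   apply(ann$cc_windows, 1, as.numeric, simplify = FALSE),
                 segments = ann$segments,
                 sequence = ann$sequence,
                 subject = ann$subject))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  data.table::fwrite(data.table::as.data.table(m[, rowmajor, drop = FALSE]),
                     path, col.names = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_eit
#' @export
read_eit <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort_format("missing sidecar metadata '%s'", sc)
  if (!file.exists(path)) abort_format("missing frame file '%s'", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$format, EIT_FORMAT_TAG)) {
    abort_format("'%s' is not an EIT frame container (format tag '%s')",
                 path, format(meta$format))
  }
  dims <- as.integer(meta$dims)
  npx <- prod(dims)
  # validation (dimensions, truncation, non-numeric cells) is done below,
  # so fread's own type-coercion chatter is silenced
  m <- suppressWarnings(data.table::fread(path, header = FALSE, sep = ",",
                                          fill = TRUE, colClasses = "numeric"))
  m <- suppressWarnings(apply(as.matrix(m), 2, as.numeric))
  if (ncol(m) != npx) {
    abort_format("frame records have %d pixels but metadata declares %d x %d = %d",
                 ncol(m), dims[1], dims[2], npx)
  }
  bad <- which(rowSums(is.na(m)) > 0)
  if (length(bad)) abort_format("frame record %d is truncated or non-numeric", bad[1])
  if (nrow(m) != meta$n_frames) {
    abort_format("found %d frame records but metadata declares %d (record %d onward missing)",
                 nrow(m), meta$n_frames, nrow(m) + 1L)
  }
  # undo row-major flattening
  rowmajor <- as.vector(t(matrix(seq_len(npx), dims[1], dims[2])))
  colmajor <- order(rowmajor)
  frames <- array(m[, colmajor, drop = FALSE], dim = c(nrow(m), dims[1], dims[2]))
  mask <- matrix(as.logical(meta$mask), dims[1], dims[2])
  ann <- meta$annotations
  ccw <- ann$cc_windows
  ccw <- if (is.null(ccw) || !length(ccw)) {
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s")))
  } else {
    w <- if (is.list(ccw)) do.call(rbind, ccw) else matrix(ccw, ncol = 2)
    dimnames(w) <- list(NULL, c("start_s", "end_s"))
    w
  }
  segs <- ann$segments
  if (!is.null(segs)) segs <- as.data.frame(segs)
  eit_recording(frames, meta$fs_hz, mask,
                list(cc_windows = ccw, segments = segs,
                     sequence = ann$sequence, subject = ann$subject))
}

#' Write / read a pressure/flow recording
#'
#' Delimited text with unit-carrying column names (`time_s`, `flow_L_s`,
#' `paw_cmH2O`, optionally `pes_cmH2O`) plus a JSON sidecar with the
#' sampling rate and ventilator settings. Round-trip is lossless to at
#' least 9 significant digits.
#'
#' @param sig A [signal_recording()].
#' @param path Table path; sidecar written as `<path>.json`.
#' @return `write_signals` returns `path` invisibly; `read_signals` the
#'   recording.
#' @export
write_signals <- function(sig, path) {
  stopifnot(inherits(sig, "signal_recording"))
  d <- data.frame(time_s = sig$time_s, flow_L_s = sig$flow_L_s,
                  paw_cmH2O = sig$paw_cmH2O)
  if (!is.null(sig$pes_cmH2O)) d$pes_cmH2O <- sig$pes_cmH2O
  meta <- list(format = SIG_FORMAT_TAG, version = FORMAT_VERSION,
               fs_hz = sig$fs_hz, vent = unclass(sig$vent))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(d, path, sep = ",")
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort_format("missing sidecar metadata '%s'", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$format, SIG_FORMAT_TAG)) {
    abort_format("'%s' is not a signal container", path)
  }
  d <- data.table::fread(path, header = TRUE, sep = ",")
  need <- c("time_s", "flow_L_s", "paw_cmH2O")
  if (!all(need %in% names(d))) {
    abort_format("signal file header must name %s (units are part of the dialect)",
                 paste(need, collapse = ", "))
  }
  if (any(diff(d$time_s) <= 0)) abort_format("time column is not strictly increasing")
  vent <- do.call(ventilator_settings, meta$vent)
  signal_recording(d$time_s, d$flow_L_s, d$paw_cmH2O,
                   if ("pes_cmH2O" %in% names(d)) d$pes_cmH2O else NULL,
                   meta$fs_hz, vent)
}

#' Write the per-condition index table
#'
#' One row per (subject, sequence, inclination) with every EIT index, in a
#' stable column order mirroring the index families of the study layout.
#'
#' @param results Data frame with columns `subject`, `sequence`,
#'   `inclination` plus the index columns of [compute_index_set()].
#' @param path Output path (comma-delimited).
#' @return `path`, invisibly.
#' @export
write_index_table <- function(results, path) {
  if (is.null(results) || !nrow(results)) abort_invalid("empty results collection")
  key <- c("subject", "sequence", "inclination")
  if (!all(key %in% names(results))) {
    abort_invalid("results must contain columns %s", paste(key, collapse = ", "))
  }
  if (anyDuplicated(results[key])) {
    abort_invalid("duplicate (subject, sequence, inclination) keys")
  }
  cols <- c(key, "n_breaths", "vt_eit_au", "ap_ratio", "pendelluft_pct_vt",
            "eeli_over_vt", "sdrvd_pct_insp_time", "gii")
  cols <- c(cols[cols %in% names(results)],
            setdiff(names(results), c(cols, "label")))
  data.table::fwrite(results[, cols, drop = FALSE], path, sep = ",")
  invisible(path)
}
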
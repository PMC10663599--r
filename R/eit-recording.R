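#' EIT recording container
#'
#' A reconstructed electrical-impedance-tomography frame stream: a
#' `time x rows x cols` array of impedance values (arbitrary units) with its
#' sampling rate, a logical lung mask, and protocol annotations
#' (chest-compression windows, inclination segments, sequence label,
#' subject id). Row 1 of the pixel grid is anterior (ventral).
#'
#' @param frames Numeric 3-D array, `time x rows x cols`.
#' @param fs_hz Frame rate (Hz), > 0.
#' @param mask Logical `rows x cols` lung mask.
#' @param annotations List with optional elements `cc_windows` (two-column
#'   matrix of start/end seconds), `segments` (data frame of inclination
#'   segments), `sequence` (label), `subject` (id).
#' @return An object of class `eit_recording`.
#' @export
eit_recording <- function(frames, fs_hz, mask = NULL, annotations = list()) {
  d <- dim(frames)
  if (length(d) != 3L) abort_invalid("frames must be a time x rows x cols array")
  if (d[1] < 2L) abort_invalid("recording must contain at least 2 frames")
  if (!is.finite(fs_hz) || fs_hz <= 0) abort_invalid("fs_hz must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!is.logical(mask) || !identical(dim(mask), d[2:3])) {
    abort_invalid("mask dimensions must match the frame grid")
  }
  dur <- d[1] / fs_hz
  for (nm in c("cc_windows")) {
    w <- annotations[[nm]]
    if (!is.null(w) && nrow(w) && any(w[, 1] < -1e-9 | w[, 2] > dur + 1e-9)) {
      abort_invalid("annotation '%s' extends beyond the recording time span", nm)
    }
  }
  structure(list(frames = frames, fs_hz = fs_hz, mask = mask,
                 annotations = annotations),
            class = "eit_recording")
}

#' @export
print.eit_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("EIT recording: %d frames @ %.2f Hz (%.1f s), %d x %d grid, %d lung pixels\n",
              d[1], x$fs_hz, d[1] / x$fs_hz, d[2], d[3], sum(x$mask)))
  if (!is.null(x$annotations$sequence)) {
    cat(sprintf("  sequence %s, subject %s\n",
                x$annotations$sequence, format(x$annotations$subject)))
  }
  ncc <- if (is.null(x$annotations$cc_windows)) 0L else nrow(x$annotations$cc_windows)
  cat(sprintf("  %d compression window(s)\n", ncc))
  invisible(x)
}

#' Plot the global impedance signal of a recording
#'
#' @param x An `eit_recording`.
#' @param filtered Overlay the compression-artifact-filtered signal.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eit_recording <- function(x, filtered = TRUE, ...) {
  g <- global_signal(x)
  t <- (seq_along(g) - 1) / x$fs_hz
  graphics::plot(t, g, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "global impedance (a.u.)", ...)
  if (filtered) {
    gf <- try(remove_cc_artifact(g, x$fs_hz), silent = TRUE)
    if (!inherits(gf, "try-error")) graphics::lines(t, gf, col = "red")
  }
  w <- x$annotations$cc_windows
  if (!is.null(w) && nrow(w)) {
    graphics::abline(v = as.vector(w), lty = 3, col = "blue")
  }
  invisible(x)
}

# time vector of a recording
rec_time <- function(rec) (seq_len(dim(rec$frames)[1]) - 1) / rec$fs_hz
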
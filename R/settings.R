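#' Ventilator settings for volume-controlled ventilation
#'
#' Describes the constant-flow volume-controlled cycle used throughout:
#' insufflation, end-inspiratory pause, passive expiration. The default is
#' 10 breaths/min with a 1 s insufflation, 1 s pause and 4 s expiration at
#' PEEP 0, and a tidal volume of 8 ml/kg predicted body weight for a 51 kg
#' subject (408 ml).
#'
#' @param tidal_volume_ml Delivered tidal volume (ml).
#' @param rate_per_min Respiratory rate (breaths/min).
#' @param t_insufflation_s Constant-flow insufflation time (s).
#' @param t_pause_s End-inspiratory pause (s).
#' @param t_expiration_s Expiratory time (s).
#' @param peep_cmH2O Positive end-expiratory pressure (cmH2O).
#' @return An object of class `ventilator_settings`.
#' @examples
#' vent <- ventilator_settings()
#' vent$rate_per_min
#' @export
ventilator_settings <- function(tidal_volume_ml = 408,
                                rate_per_min = 10,
                                t_insufflation_s = 1,
                                t_pause_s = 1,
                                t_expiration_s = 4,
                                peep_cmH2O = 0) {
  durs <- c(t_insufflation_s, t_pause_s, t_expiration_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort_invalid("all cycle durations must be positive")
  }
  if (!is.finite(rate_per_min) || rate_per_min <= 0) {
    abort_invalid("rate_per_min must be positive")
  }
  if (abs(60 / rate_per_min - sum(durs)) > 1e-9) {
    abort_invalid("cycle durations (%.3f s) inconsistent with rate %.3f/min (%.3f s)",
                  sum(durs), rate_per_min, 60 / rate_per_min)
  }
  if (!is.finite(peep_cmH2O) || peep_cmH2O < 0) abort_invalid("peep_cmH2O must be >= 0")
  if (!is.finite(tidal_volume_ml) || tidal_volume_ml <= 0) {
    abort_invalid("tidal_volume_ml must be positive")
  }
  structure(list(tidal_volume_ml = tidal_volume_ml,
                 rate_per_min = rate_per_min,
                 t_insufflation_s = t_insufflation_s,
                 t_pause_s = t_pause_s,
                 t_expiration_s = t_expiration_s,
                 peep_cmH2O = peep_cmH2O),
            class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf("Volume-controlled ventilation: VT %g ml, %g/min (I %g s / pause %g s / E %g s), PEEP %g cmH2O\n",
              x$tidal_volume_ml, x$rate_per_min, x$t_insufflation_s,
              x$t_pause_s, x$t_expiration_s, x$peep_cmH2O))
  invisible(x)
}

#' Mechanical chest-compression settings
#'
#' Compression rate, artifact amplitude and the time windows during which
#' compressions run. Compressions are asynchronous with the ventilator
#' (the device runs at its own fixed rate, 102/min by default).
#'
#' @param rate_per_min Compression rate (events/min).
#' @param depth_scale Artifact amplitude as a fraction of each pixel's tidal
#'   amplitude (arbitrary units per unit weight).
#' @param windows Two-column matrix (or list of length-2 vectors) of
#'   `(start_s, end_s)` compression windows; may be empty.
#' @param synchronized Logical; compressions synchronized with the ventilator
#'   (always `FALSE` for the mechanical device modelled here).
#' @return An object of class `compression_settings`.
#' @examples
#' cc <- compression_settings(windows = cbind(60, 120))
#' @export
compression_settings <- function(rate_per_min = 102,
                                 depth_scale = 0.5,
                                 windows = matrix(numeric(0), ncol = 2),
                                 synchronized = FALSE) {
  if (!is.finite(rate_per_min) || rate_per_min <= 0) {
    abort_invalid("rate_per_min must be positive")
  }
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2)
  colnames(windows) <- c("start_s", "end_s")
  if (nrow(windows)) {
    if (any(windows[, 2] <= windows[, 1])) abort_invalid("compression windows must have end > start")
    o <- order(windows[, 1])
    windows <- windows[o, , drop = FALSE]
    if (nrow(windows) > 1 &&
        any(windows[-1, 1] < windows[-nrow(windows), 2])) {
      abort_invalid("compression windows must be disjoint")
    }
  }
  structure(list(rate_per_min = rate_per_min,
                 depth_scale = depth_scale,
                 windows = windows,
                 synchronized = isTRUE(synchronized)),
            class = "compression_settings")
}

#' @export
print.compression_settings <- function(x, ...) {
  cat(sprintf("Chest compressions: %g/min, depth scale %g, %d window(s), %s\n",
              x$rate_per_min, x$depth_scale, nrow(x$windows),
              if (x$synchronized) "synchronized" else "asynchronous"))
  invisible(x)
}
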
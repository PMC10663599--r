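#' Synchronized pressure/flow recording
#'
#' Aligned 200-Hz (by default) flow, airway-pressure and esophageal-pressure
#' traces with the ventilator settings they were acquired under.
#'
#' @param time_s,flow_L_s,paw_cmH2O,pes_cmH2O Aligned numeric columns
#'   (`pes_cmH2O` may be `NULL` when the esophageal catheter is absent).
#' @param fs_hz Sampling rate (Hz), consistent with the time step.
#' @param vent A [ventilator_settings()] object.
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(time_s, flow_L_s, paw_cmH2O, pes_cmH2O = NULL,
                             fs_hz, vent = ventilator_settings()) {
  n <- length(time_s)
  if (length(flow_L_s) != n || length(paw_cmH2O) != n ||
      (!is.null(pes_cmH2O) && length(pes_cmH2O) != n)) {
    abort_invalid("signal columns must have equal length")
  }
  if (n >= 2 && any(diff(time_s) <= 0)) abort_invalid("time column must be strictly increasing")
  if (n >= 2 && abs(stats::median(diff(time_s)) - 1 / fs_hz) > 0.01 / fs_hz) {
    abort_invalid("time step inconsistent with fs_hz")
  }
  structure(list(time_s = time_s, flow_L_s = flow_L_s,
                 paw_cmH2O = paw_cmH2O, pes_cmH2O = pes_cmH2O,
                 fs_hz = fs_hz, vent = vent),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("Pressure/flow recording: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$time_s), x$fs_hz, length(x$time_s) / x$fs_hz,
              if (is.null(x$pes_cmH2O)) ", no esophageal trace" else ""))
  invisible(x)
}

#' Simulate ventilator pressure/flow waveforms
#'
#' Single-compartment linear respiratory model under volume-controlled
#' constant-flow ventilation. Elastances add: `E_rs = E_L + E_CW`
#' (equivalently `1/C_rs = 1/C_L + 1/C_CW`). During insufflation flow is
#' constant and delivers the set tidal volume; flow is zero during the
#' end-inspiratory pause; expiration is passive with time constant
#' `R * C_rs`. Airway pressure is `PEEP + R * flow + V / C_rs`; esophageal
#' pressure is `V / C_CW` plus a constant offset. A short pre-breath
#' lead-in at end-expiratory conditions precedes the first cycle so
#' baseline pressures can be sampled.
#'
#' @param subject A [subject_params()] (supplies compliances/resistance).
#' @param vent A [ventilator_settings()].
#' @param fs_hz Sampling rate (Hz), >= 50.
#' @param n_breaths Number of cycles (>= 1).
#' @param seed Seed for the optional noise.
#' @param noise_frac Gaussian noise SD as a fraction of each channel's
#'   amplitude (0 = noiseless).
#' @param pes_offset_cmH2O Constant esophageal baseline offset.
#' @param lead_in_s Pre-breath baseline duration (s).
#' @param include_pes Set `FALSE` to omit the esophageal channel.
#' @return A [signal_recording()].
#' @examples
#' sig <- simulate_pressure_flow(subject_params(), n_breaths = 2, seed = 1)
#' range(sig$paw_cmH2O)
#' @export
simulate_pressure_flow <- function(subject = subject_params(),
                                   vent = ventilator_settings(),
                                   fs_hz = 200, n_breaths = 5, seed = 1,
                                   noise_frac = 0,
                                   pes_offset_cmH2O = 5,
                                   lead_in_s = 0.5,
                                   include_pes = TRUE) {
  if (fs_hz < 50) abort_invalid("fs_hz must be at least 50 Hz")
  if (n_breaths < 1) abort_invalid("n_breaths must be >= 1")
  cl <- subject$lung_compliance_ml_cmH2O
  ccw <- subject$chestwall_compliance_ml_cmH2O
  r <- subject$resistance_cmH2O_s_L
  if (cl <= 0 || ccw <= 0 || r <= 0) abort_invalid("compliances and resistance must be positive")
  crs <- 1 / (1 / cl + 1 / ccw)                  # ml/cmH2O; elastances add
  tau <- r * crs / 1000                          # s (R in cmH2O s/L, C in ml/cmH2O)
  vt <- vent$tidal_volume_ml
  ti <- vent$t_insufflation_s; tp <- vent$t_pause_s; te <- vent$t_expiration_s
  tcyc <- ti + tp + te
  t <- seq(0, lead_in_s + n_breaths * tcyc - 1 / fs_hz, by = 1 / fs_hz)
  ph <- (t - lead_in_s) %% tcyc
  ph[t < lead_in_s] <- tcyc - 1e-9               # treat lead-in as late expiration
  insp <- ph < ti
  pause <- !insp & ph < ti + tp
  expn <- !(insp | pause)
  flow <- numeric(length(t))
  vol <- numeric(length(t))
  flow[insp] <- vt / 1000 / ti                   # L/s
  vol[insp] <- vt * ph[insp] / ti
  vol[pause] <- vt
  vol[expn] <- vt * exp(-(ph[expn] - ti - tp) / tau)
  flow[expn] <- -vol[expn] / (tau * 1000)
  vol[t < lead_in_s] <- 0
  flow[t < lead_in_s] <- 0
  paw <- vent$peep_cmH2O + r * flow + vol / crs
  pes <- vol / ccw + pes_offset_cmH2O
  if (noise_frac > 0) {
    with_seed(seed, {
      for (nm in c("flow", "paw", "pes")) {
        v <- get(nm)
        assign(nm, v + stats::rnorm(length(v), sd = noise_frac * diff(range(v))))
      }
    })
  }
  signal_recording(t, flow, paw, if (include_pes) pes else NULL, fs_hz, vent)
}
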
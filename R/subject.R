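#' Elliptical two-lung region of interest
#'
#' Builds a logical pixel mask with two elliptical lung fields on an
#' `rows x cols` reconstruction grid. Row 1 is anterior (ventral); columns
#' run left to right. Lung centres sit slightly posterior of the grid
#' midline, as in transverse thoracic sections.
#'
#' @param rows,cols Grid dimensions (>= 8 each).
#' @return Logical matrix of dimension `rows x cols`.
#' @examples
#' m <- lung_mask(32, 32)
#' sum(m)
#' @export
lung_mask <- function(rows = 32, cols = 32) {
  if (rows < 8 || cols < 8) abort_invalid("grid dimensions must be at least 8 x 8")
  r <- (seq_len(rows) - 0.5) / rows   # 0 anterior .. 1 posterior
  c <- (seq_len(cols) - 0.5) / cols
  rr <- matrix(r, rows, cols)
  cc <- matrix(c, rows, cols, byrow = TRUE)
  in_ellipse <- function(c0, r0, a, b) ((cc - c0) / a)^2 + ((rr - r0) / b)^2 <= 1
  in_ellipse(0.30, 0.55, 0.17, 0.33) | in_ellipse(0.70, 0.55, 0.17, 0.33)
}

#' Synthetic subject parameters with known ground truth
#'
#' Bundles everything the generator needs for one subject: the pixel grid
#' and lung mask, the per-pixel tidal amplitude map, the antiphase
#' (pendelluft) pixel set, the per-pixel inflation-onset delay map, the
#' end-expiratory impedance drift injected during chest-compression windows,
#' per-inclination tidal scaling factors, the pixel noise level, and the
#' respiratory-mechanics parameters used for the pressure/flow generator.
#'
#' Defaults emulate the measurement situation the pipeline targets: an
#' anterior-dominant tidal distribution (ventilation skewed ventrally, as
#' under general anaesthesia with dorsal atelectasis), a small posterior
#' pendelluft region in antiphase with the ventilator carrying
#' `pendelluft_fraction` of the net tidal impedance change, inflation-onset
#' delays increasing linearly toward the posterior rows, an EELI fall of
#' about 1.2 tidal amplitudes during compressions, and a tidal reduction at
#' 35 deg trunk inclination.
#'
#' @param grid_dims Integer vector `(rows, cols)`, each >= 8.
#' @param mask Logical lung mask; default [lung_mask()] on `grid_dims`.
#' @param base_amplitude_au Mean pixel tidal amplitude (a.u.).
#' @param anterior_weight Relative amplitude slope: pixel amplitude scales
#'   linearly from `1 + anterior_weight` (anterior row) to
#'   `1 - anterior_weight` (posterior row). Must be in `[0, 1)`.
#' @param pendelluft_fraction Fraction of net global tidal impedance carried
#'   by antiphase pixels; the resulting pendelluft index truth is
#'   `-100 * pendelluft_fraction` %VT_EIT. Set 0 for none.
#' @param max_delay_frac Posterior-most inflation-onset delay as a fraction
#'   of insufflation time; delays rise linearly with row depth. In `[0, 1)`.
#' @param eeli_drift Length-2 numeric `(magnitude_au, time_constant_s)`:
#'   first-order EELI fall during compression windows.
#' @param inclination_effect Named numeric vector of multiplicative tidal
#'   factors per trunk angle (names are angles in degrees).
#' @param noise_sd Per-pixel white-noise standard deviation (a.u.).
#' @param lung_compliance_ml_cmH2O,chestwall_compliance_ml_cmH2O Lung and
#'   chest-wall compliance (ml/cmH2O).
#' @param resistance_cmH2O_s_L Airway resistance (cmH2O s/L).
#' @return An object of class `subject_params`.
#' @examples
#' sp <- subject_params()
#' sp$grid_dims
#' @export
subject_params <- function(grid_dims = c(32, 32),
                           mask = NULL,
                           base_amplitude_au = 10,
                           anterior_weight = 0.4,
                           pendelluft_fraction = 0.08,
                           max_delay_frac = 0.3,
                           eeli_drift = c(NA, 10),
                           inclination_effect = c("0" = 1, "18" = 0.95, "35" = 0.55),
                           noise_sd = 0.5,
                           lung_compliance_ml_cmH2O = 50,
                           chestwall_compliance_ml_cmH2O = 100,
                           resistance_cmH2O_s_L = 10) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 2L || any(grid_dims < 8L)) {
    abort_invalid("grid_dims must be two integers, each >= 8")
  }
  rows <- grid_dims[1]; cols <- grid_dims[2]
  if (is.null(mask)) mask <- lung_mask(rows, cols)
  if (!is.logical(mask) || !identical(dim(mask), grid_dims)) {
    abort_invalid("mask must be a logical matrix matching grid_dims")
  }
  if (!any(mask)) abort_invalid("lung mask is empty")
  if (anterior_weight < 0 || anterior_weight >= 1) {
    abort_invalid("anterior_weight must be in [0, 1)")
  }
  if (max_delay_frac < 0 || max_delay_frac >= 1) {
    abort_invalid("max_delay_frac must be in [0, 1)")
  }
  if (pendelluft_fraction < 0) abort_invalid("pendelluft_fraction must be >= 0")
  if (lung_compliance_ml_cmH2O <= 0 || chestwall_compliance_ml_cmH2O <= 0 ||
      resistance_cmH2O_s_L <= 0) {
    abort_invalid("compliances and resistance must be positive")
  }

  row_frac <- (row(mask) - 1) / (rows - 1)        # 0 anterior .. 1 posterior
  amp <- matrix(0, rows, cols)
  amp[mask] <- base_amplitude_au * (1 + anterior_weight * (1 - 2 * row_frac[mask]))

  # Pendelluft region: a posterior blob inside the mask, scaled so that the
  # summed antiphase amplitude is pendelluft_fraction of the NET global tidal
  # amplitude (so the downstream index truth is exactly -100 * fraction).
  pend <- matrix(FALSE, rows, cols)
  if (pendelluft_fraction > 0) {
    cand <- mask & row_frac >= 0.65 & row_frac <= 0.85
    if (!any(cand)) abort_invalid("no posterior pixels available for pendelluft region")
    pend <- cand
    pos_sum <- sum(amp[mask & !pend])
    # sum_pend = f/(1+f) * pos_sum  =>  sum_pend = f * (pos_sum - sum_pend)
    target <- pendelluft_fraction / (1 + pendelluft_fraction) * pos_sum
    amp[pend] <- amp[pend] * target / sum(amp[pend])
  }

  delay <- matrix(0, rows, cols)
  delay[mask] <- max_delay_frac * row_frac[mask]
  delay[pend] <- 0

  net_vt <- sum(amp[mask & !pend]) - sum(amp[pend])
  if (is.na(eeli_drift[1])) eeli_drift[1] <- 1.2 * net_vt
  if (length(eeli_drift) != 2L || any(!is.finite(eeli_drift)) || eeli_drift[2] <= 0) {
    abort_invalid("eeli_drift must be (magnitude_au, time_constant_s) with positive time constant")
  }
  if (is.null(names(inclination_effect))) {
    abort_invalid("inclination_effect must be named by trunk angle (degrees)")
  }

  structure(list(grid_dims = grid_dims,
                 mask = mask,
                 tidal_amplitude_map = amp,
                 pendelluft_pixels = pend,
                 delay_map = delay,
                 eeli_drift = as.numeric(eeli_drift),
                 inclination_effect = inclination_effect,
                 noise_sd = noise_sd,
                 lung_compliance_ml_cmH2O = lung_compliance_ml_cmH2O,
                 chestwall_compliance_ml_cmH2O = chestwall_compliance_ml_cmH2O,
                 resistance_cmH2O_s_L = resistance_cmH2O_s_L),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("Synthetic subject: %d x %d grid, %d lung pixels (%d antiphase)\n",
              x$grid_dims[1], x$grid_dims[2], sum(x$mask), sum(x$pendelluft_pixels)))
  cat(sprintf("  net tidal amplitude %.1f a.u.; EELI drift %.1f a.u. (tau %.1f s)\n",
              subject_vt_truth(x), x$eeli_drift[1], x$eeli_drift[2]))
  cat(sprintf("  C_L %.0f, C_CW %.0f ml/cmH2O; R %.0f cmH2O s/L\n",
              x$lung_compliance_ml_cmH2O, x$chestwall_compliance_ml_cmH2O,
              x$resistance_cmH2O_s_L))
  invisible(x)
}

# Net global tidal amplitude: positive pixels minus antiphase pixels.
subject_vt_truth <- function(subject) {
  sum(subject$tidal_amplitude_map[subject$mask & !subject$pendelluft_pixels]) -
    sum(subject$tidal_amplitude_map[subject$pendelluft_pixels])
}

# Signed per-pixel tidal amplitude map (antiphase pixels negative).
subject_signed_map <- function(subject) {
  m <- subject$tidal_amplitude_map
  m[subject$pendelluft_pixels] <- -m[subject$pendelluft_pixels]
  m[!subject$mask] <- 0
  m
}
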
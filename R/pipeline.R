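#' Configuration for a simulation/analysis run
#'
#' Collects every tunable of the pipeline in one place so a run manifest
#' fully reproduces a run. Per-subject seeds are derived deterministically
#' from the master seed.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed.
#' @param grid_dims EIT reconstruction grid.
#' @param time_scale Multiplies all protocol segment durations (1 = full
#'   timeline; smaller values give fast reduced runs).
#' @param fs_eit_hz,fs_sig_hz EIT frame rate and pressure/flow sampling rate.
#' @param cc_rate_per_min Mechanical compression rate.
#' @param noise_sd Pixel noise SD (a.u.).
#' @param pendelluft_fraction,max_delay_frac,anterior_weight See
#'   [subject_params()].
#' @param between_subject_cv Log-normal coefficient of variation applied to
#'   per-subject tidal amplitude (and compliances).
#' @param compliance_shift_ml_cmH2O Named length-2 numeric: after-minus-
#'   before compression change injected into lung and chest-wall compliance.
#' @param mech_breaths Breaths per mechanics phase.
#' @param filter_cutoff_hz Explicit filter cutoff (NULL = automatic).
#' @param write_recordings Write every simulated recording/signal file to
#'   the output tree (off by default; the frame files are large).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 7, seed = 1,
                       grid_dims = c(32, 32), time_scale = 1,
                       fs_eit_hz = 13.58, fs_sig_hz = 200,
                       cc_rate_per_min = 102,
                       noise_sd = 0.5,
                       pendelluft_fraction = 0.08,
                       max_delay_frac = 0.3,
                       anterior_weight = 0.4,
                       between_subject_cv = 0.2,
                       compliance_shift_ml_cmH2O = c(lung = 6, chestwall = 25),
                       mech_breaths = 4,
                       filter_cutoff_hz = NULL,
                       write_recordings = FALSE) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_invalid("n_subjects must be a positive integer")
  }
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-(subject, stream) seed below 2^31
derive_seed <- function(master, i, j = 0) {
  as.integer((as.numeric(master) * 1000003 + i * 10007 + j * 101) %% 2147483646 + 1)
}

peep_of_sequence <- function(sequence) {
  switch(sequence,
         "noCPR-PEEP0" = 0, "CPR-PEEP0" = 0, "CPR-PEEP5" = 5,
         "CPR-PEEP10" = 10, "CPR-PEEP0-ITD" = 0,
         abort_invalid("unknown sequence '%s'", sequence))
}

has_cc <- function(sequence) !startsWith(sequence, "noCPR")

# subject with between-subject variability applied
draw_subject <- function(cfg, i) {
  with_seed(derive_seed(cfg$seed, i, 1), {
    f <- exp(stats::rnorm(1, 0, cfg$between_subject_cv))
    fc <- exp(stats::rnorm(2, 0, cfg$between_subject_cv / 2))
    subject_params(grid_dims = cfg$grid_dims,
                   base_amplitude_au = 10 * f,
                   anterior_weight = cfg$anterior_weight,
                   pendelluft_fraction = cfg$pendelluft_fraction,
                   max_delay_frac = cfg$max_delay_frac,
                   noise_sd = cfg$noise_sd,
                   lung_compliance_ml_cmH2O = 50 * fc[1],
                   chestwall_compliance_ml_cmH2O = 100 * fc[2])
  })
}

#' Run the full simulation study
#'
#' Simulates the complete protocol (every subject x sequence with the
#' flat / 18 deg / 35 deg timeline), runs the analysis chain on each
#' recording, and writes the result tables: the per-condition index table,
#' per-breath mechanics, before/after-compression compliance changes, and
#' the random-intercept model fits with residual diagnostics. Ground truth
#' and a run manifest are written alongside. Deterministic under a fixed
#' master seed; a failure in one sequence does not stop the others (it is
#' recorded in the manifest).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the tables (`index_table`,
#'   `mechanics`, `compliance_change`, `model_fits`, `failures`).
#' @export
run_simulation_study <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- make_protocol(config$n_subjects, seed = config$seed,
                            time_scale = config$time_scale)
  asg <- protocol$assignments
  index_rows <- list(); mech_rows <- list(); truth_list <- list()
  failures <- list()
  if (config$write_recordings) {
    dir.create(file.path(out_dir, "recordings"), showWarnings = FALSE)
  }

  for (i in protocol$subjects) {
    subject <- draw_subject(config, i)
    for (sq in asg$sequence[asg$subject == i]) {
      res <- tryCatch({
        segs <- protocol$segments
        cc_on <- has_cc(sq)
        ccw <- if (cc_on) segments_cc_windows(segs) else
          matrix(numeric(0), ncol = 2)
        subj_run <- subject
        if (!cc_on) {
          # without compressions tidal volume is stable across inclinations
          # and there is no compression-induced end-expiratory fall
          subj_run$inclination_effect[] <- 1
          subj_run$eeli_drift[1] <- 0
        }
        vent <- ventilator_settings(peep_cmH2O = peep_of_sequence(sq))
        cc <- compression_settings(rate_per_min = config$cc_rate_per_min,
                                   windows = ccw)
        sim <- simulate_eit_recording(
          subj_run, vent, cc, fs_hz = config$fs_eit_hz,
          duration_s = max(segs$end_s), seed = derive_seed(config$seed, i, 2),
          segments = segs, sequence = sq, subject_id = i)
        idx <- compute_index_set(sim$recording,
                                 cc_rate_per_min = config$cc_rate_per_min,
                                 cutoff_hz = config$filter_cutoff_hz)
        idx <- cbind(subject = i, sequence = sq, idx)

        # mechanics in the compression-free time: flat before/after, and
        # before-elevation (18 deg) vs after-elevation (35 deg)
        shift <- config$compliance_shift_ml_cmH2O
        mech <- lapply(c(before_flat = 0, after_flat = 1,
                         before_elev = 0, after_elev = 1), function(sh) {
          sp <- subject
          if (sh && cc_on) {
            sp$lung_compliance_ml_cmH2O <- sp$lung_compliance_ml_cmH2O + shift[["lung"]]
            sp$chestwall_compliance_ml_cmH2O <- sp$chestwall_compliance_ml_cmH2O + shift[["chestwall"]]
          }
          sp
        })
        mech <- lapply(seq_along(mech), function(k) {
          sig <- simulate_pressure_flow(mech[[k]], vent,
                                        fs_hz = config$fs_sig_hz,
                                        n_breaths = config$mech_breaths,
                                        seed = derive_seed(config$seed, i, 10 + k))
          cm <- compliance(sig)
          cbind(subject = i, sequence = sq,
                phase = c("before_flat", "after_flat",
                          "before_elev", "after_elev")[k],
                cm[cm$valid, , drop = FALSE])
        })
        if (config$write_recordings) {
          write_eit(sim$recording,
                    file.path(out_dir, "recordings",
                              sprintf("subject%02d_%s.eit", i, sq)))
        }
        list(idx = idx, mech = do.call(rbind, mech), truth = sim$truth)
      }, error = function(e) e)
      key <- sprintf("subject%02d_%s", i, sq)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        index_rows[[key]] <- res$idx
        mech_rows[[key]] <- res$mech
        truth_list[[key]] <- list(
          vt_eit_au = res$truth$vt_eit_au,
          pendelluft_pct_vt = res$truth$pendelluft_pct_vt,
          ap_ratio = res$truth$ap_ratio, gii = res$truth$gii,
          sdrvd_pct = res$truth$sdrvd_pct,
          eeli_over_vt_cc = res$truth$eeli_over_vt_cc)
      }
    }
  }
  if (!length(index_rows)) abort_invalid("every sequence failed: %s",
                                         paste(unlist(failures), collapse = "; "))
  index_table <- do.call(rbind, c(index_rows, make.row.names = FALSE))
  mech_table <- do.call(rbind, c(mech_rows, make.row.names = FALSE))

  # Table-2-shaped compliance changes per sequence (flat and elevation)
  cc_change <- list()
  for (sq in setdiff(eitcpr_sequences(), "noCPR-PEEP0")) {
    for (pos in c("flat", "elev")) {
      bt <- mech_table[mech_table$sequence == sq &
                         mech_table$phase == paste0("before_", pos), ]
      at <- mech_table[mech_table$sequence == sq &
                         mech_table$phase == paste0("after_", pos), ]
      if (!nrow(bt) || !nrow(at)) next
      for (oc in c("c_lung_ml_cmH2O", "c_cw_ml_cmH2O")) {
        ch <- tryCatch(compliance_change(bt, at, oc), error = function(e) NULL)
        if (is.null(ch)) next
        cc_change[[length(cc_change) + 1L]] <- data.frame(
          sequence = sq, position = if (pos == "flat") "Flat" else "Elevation",
          outcome = oc, change = ch$estimate,
          ci_low = ch$ci[1], ci_high = ch$ci[2], p = ch$p,
          n_subjects = ch$n_pairs)
      }
    }
  }
  cc_change <- if (length(cc_change)) do.call(rbind, cc_change) else NULL

  # random-intercept inclination models per sequence and outcome
  fits <- list(); resid_rows <- list()
  if (config$n_subjects >= 2) {
    for (sq in unique(index_table$sequence)) {
      for (oc in c("vt_eit_au", "ap_ratio", "pendelluft_pct_vt",
                   "eeli_over_vt")) {
        ft <- tryCatch(fit_inclination_model(index_table, oc, sequence = sq),
                       error = function(e) NULL)
        if (is.null(ft)) next
        co <- ft$coefficients
        fits[[length(fits) + 1L]] <- data.frame(
          sequence = sq, outcome = oc, term = rownames(co), co,
          degraded = ft$degraded, row.names = NULL)
        resid_rows[[length(resid_rows) + 1L]] <- data.frame(
          sequence = sq, outcome = oc,
          fitted = ft$fitted, residual = ft$residuals, row.names = NULL)
      }
    }
  }
  model_fits <- if (length(fits)) do.call(rbind, fits) else NULL

  write_index_table(index_table, file.path(out_dir, "index_table.csv"))
  data.table::fwrite(mech_table, file.path(out_dir, "mechanics_breaths.csv"))
  if (!is.null(cc_change)) {
    data.table::fwrite(cc_change, file.path(out_dir, "compliance_change.csv"))
  }
  if (!is.null(model_fits)) {
    data.table::fwrite(model_fits, file.path(out_dir, "model_fits.csv"))
    data.table::fwrite(do.call(rbind, resid_rows),
                       file.path(out_dir, "model_residuals.csv"))
  }
  jsonlite::write_json(truth_list, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "eitcpr",
                   version = as.character(utils::packageVersion("eitcpr")),
                   config = unclass(config),
                   failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(index_table = index_table, mechanics = mech_table,
                 compliance_change = cc_change, model_fits = model_fits,
                 failures = failures))
}

#' Analyze previously written recordings
#'
#' Reads every EIT frame container under `path` (files with a matching
#' JSON sidecar), runs the index chain on each, fits the inclination
#' models, and writes the same tables as the simulation path (minus
#' ground-truth comparison). Malformed files are reported per file and do
#' not stop the run.
#'
#' @param path Directory containing `.eit` containers (or a character
#'   vector of file paths).
#' @param config A [run_config()] (filter settings are honoured).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `index_table`, `model_fits` and
#'   `errors` (named character vector of per-file failures).
#' @export
run_analysis <- function(path, config = run_config(), out_dir) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.eit$", recursive = TRUE, full.names = TRUE)
  } else path
  if (!length(files)) abort_invalid("no recordings found under '%s'", path[1])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  index_rows <- list(); errors <- character(0)
  for (f in files) {
    res <- tryCatch({
      rec <- read_eit(f)
      idx <- compute_index_set(rec,
                               cc_rate_per_min = config$cc_rate_per_min,
                               cutoff_hz = config$filter_cutoff_hz)
      cbind(subject = rec$annotations$subject %||% NA,
            sequence = rec$annotations$sequence %||% NA_character_, idx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[f] <- conditionMessage(res)
    } else index_rows[[f]] <- res
  }
  if (!length(index_rows)) {
    abort_invalid("no readable recordings: %s", paste(errors, collapse = "; "))
  }
  index_table <- do.call(rbind, c(index_rows, make.row.names = FALSE))
  fits <- list()
  if (length(unique(index_table$subject)) >= 2) {
    for (sq in unique(index_table$sequence)) {
      for (oc in c("vt_eit_au", "ap_ratio", "pendelluft_pct_vt", "eeli_over_vt")) {
        ft <- tryCatch(fit_inclination_model(index_table, oc, sequence = sq),
                       error = function(e) NULL)
        if (is.null(ft)) next
        co <- ft$coefficients
        fits[[length(fits) + 1L]] <- data.frame(
          sequence = sq, outcome = oc, term = rownames(co), co,
          degraded = ft$degraded, row.names = NULL)
      }
    }
  }
  model_fits <- if (length(fits)) do.call(rbind, fits) else NULL
  write_index_table(index_table, file.path(out_dir, "index_table.csv"))
  if (!is.null(model_fits)) {
    data.table::fwrite(model_fits, file.path(out_dir, "model_fits.csv"))
  }
  if (length(errors)) {
    jsonlite::write_json(as.list(errors), file.path(out_dir, "errors.json"),
                         auto_unbox = TRUE)
  }
  invisible(list(index_table = index_table, model_fits = model_fits,
                 errors = errors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
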
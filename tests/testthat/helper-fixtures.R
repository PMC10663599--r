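# Small fixtures shared across tests; everything is generated in code.

FS_EIT <- 13.58

small_subject <- function(noise_sd = 0, pendelluft_fraction = 0.08,
                          max_delay_frac = 0.3, ...) {
  subject_params(grid_dims = c(16, 16), noise_sd = noise_sd,
                 pendelluft_fraction = pendelluft_fraction,
                 max_delay_frac = max_delay_frac, ...)
}

# a plain ventilation recording: no compressions, optionally noiseless
quiet_sim <- function(duration_s = 30, noise_sd = 0, seed = 1, ...) {
  simulate_eit_recording(small_subject(noise_sd = noise_sd, ...),
                         cc = compression_settings(),
                         duration_s = duration_s, seed = seed)
}

# recording with one compression bout and a pre-compression baseline
cc_sim <- function(subject = subject_params(), cc_windows = cbind(30, 90),
                   duration_s = 96, seed = 1) {
  simulate_eit_recording(subject,
                         cc = compression_settings(windows = cc_windows),
                         duration_s = duration_s, seed = seed)
}

# hand-built frame stack from a list of matrices
frames_from <- function(mats) {
  d <- dim(mats[[1]])
  arr <- array(0, dim = c(length(mats), d[1], d[2]))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

# single-breath descriptor for hand-built frames
manual_breath <- function(onset, top, end = top) {
  data.frame(onset_idx = onset, max_idx = top, end_insp_idx = top,
             end_exp_idx = end, onset_s = 0,
             vt_eit_au = NA_real_, eeli_au = NA_real_)
}
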
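#' @rdname make_protocol
#' @export
eitcpr_sequences <- function() {
  c("noCPR-PEEP0", "CPR-PEEP0", "CPR-PEEP5", "CPR-PEEP10", "CPR-PEEP0-ITD")
}

#' Multi-subject protocol design
#'
#' Assigns the five experimental sequences (`noCPR-PEEP0`, `CPR-PEEP0`,
#' `CPR-PEEP5`, `CPR-PEEP10`, `CPR-PEEP0-ITD`) to each subject in randomized
#' order, each sequence carrying the fixed inclination timeline
#' flat -> 18 deg -> 35 deg with chest-compression windows: 1 min of
#' compressions flat, 1 min at 18 deg, compressions continued through a
#' 2-min elevation ramp, then 90 s at 35 deg. The timeline also includes
#' compression-free epochs before and after the flat compression bout and
#' after the 35 deg bout, used for respiratory mechanics.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed controlling the per-subject sequence permutations.
#' @param time_scale Multiplies all segment durations (useful for fast small
#'   runs; 1 reproduces the full timeline).
#' @return An object of class `protocol_design`: a list with `subjects`,
#'   `assignments` (data frame subject/order/sequence) and `segments`
#'   (per-sequence timeline template with angles, compression flags and
#'   measurement epochs).
#' @examples
#' pd <- make_protocol(7, seed = 1)
#' nrow(pd$assignments)  # 35 sequence instances
#' @export
make_protocol <- function(n_subjects, seed = 1, time_scale = 1) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 1) {
    abort_invalid("n_subjects must be a positive integer")
  }
  n_subjects <- as.integer(n_subjects)
  seqs <- eitcpr_sequences()
  assignments <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      data.frame(subject = i, order = seq_along(seqs),
                 sequence = sample(seqs), stringsAsFactors = FALSE)
    }))
  })
  structure(list(subjects = seq_len(n_subjects),
                 assignments = assignments,
                 segments = protocol_segments(time_scale = time_scale),
                 seed = seed,
                 time_scale = time_scale),
            class = "protocol_design")
}

#' Per-sequence inclination/compression timeline
#'
#' The segment template applied within every sequence. Angles follow the
#' fixed order flat, 18, 35 deg; `cc` marks chest-compression segments
#' (ignored for the no-CPR sequence); `measure` marks the 60-s windows on
#' which EIT indexes are computed; `ramp` marks the continuous 18 -> 35 deg
#' elevation. The elevation ramp rate is a parameter of the timeline
#' (`ramp_s`), 120 s by default for the 17-degree change.
#'
#' @param time_scale Multiplies all durations.
#' @param ramp_s Duration of the 18 -> 35 deg elevation (s).
#' @return Data frame with columns `label`, `angle_start`, `angle_end`,
#'   `cc`, `measure`, `ramp`, `start_s`, `end_s`.
#' @export
protocol_segments <- function(time_scale = 1, ramp_s = 120) {
  durs <- c(flat_baseline = 60, flat_cc = 60, flat_post = 30,
            incl18_cc = 60, ramp_cc = ramp_s, incl35_cc = 90, post35 = 30)
  durs <- durs * time_scale
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  data.frame(label = names(durs),
             angle_start = c(0, 0, 0, 18, 18, 35, 35),
             angle_end   = c(0, 0, 0, 18, 35, 35, 35),
             cc      = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
             measure = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
             ramp    = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
             start_s = unname(starts), end_s = unname(ends),
             stringsAsFactors = FALSE)
}

#' @export
print.protocol_design <- function(x, ...) {
  cat(sprintf("Protocol design: %d subject(s) x %d sequences (seed %s)\n",
              length(x$subjects), length(eitcpr_sequences()),
              format(x$seed)))
  cat(sprintf("  timeline: %s (total %.0f s per sequence)\n",
              paste(x$segments$label, collapse = " > "),
              max(x$segments$end_s)))
  invisible(x)
}

# Contiguous cc segments merged into (start_s, end_s) compression windows.
segments_cc_windows <- function(segments) {
  cc <- segments[segments$cc, , drop = FALSE]
  if (!nrow(cc)) return(matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("start_s", "end_s"))))
  runs <- cumsum(c(TRUE, cc$start_s[-1] > cc$end_s[-nrow(cc)] + 1e-9))
  out <- t(vapply(split(seq_len(nrow(cc)), runs), function(i) {
    c(min(cc$start_s[i]), max(cc$end_s[i]))
  }, numeric(2)))
  colnames(out) <- c("start_s", "end_s")
  out
}
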
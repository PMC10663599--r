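# Classed conditions used throughout the package so callers can distinguish
# user errors (bad arguments, malformed files) from degenerate analysis
# states (undefined indexes) programmatically.

abort_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eitcpr_invalid_argument", "eitcpr_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eitcpr_format_error", "eitcpr_error")))
}

abort_infeasible_filter <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eitcpr_infeasible_filter", "eitcpr_error")))
}

abort_undefined <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eitcpr_undefined", "eitcpr_error")))
}

warn_eitcpr <- function(msg, ..., class = "eitcpr_warning") {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "eitcpr_warning")))
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort_invalid("`seed` must be a single integer")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
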
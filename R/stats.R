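#' Random-intercept model of an index across trunk inclinations
#'
#' Fits `outcome ~ inclination` with a per-subject random intercept
#' (restricted maximum likelihood), inclination as a categorical fixed
#' effect with flat as the reference level, and reports Wald t-tests for
#' the 18-deg-vs-flat and 35-deg-vs-flat contrasts with within-subject
#' denominator degrees of freedom. If the mixed fit fails (e.g. zero
#' between-subject variance on degenerate data) the fit degrades to a
#' fixed-effects-only linear model with a `degraded` flag rather than
#' failing.
#'
#' @param table Data frame with columns `subject`, `inclination` (0/18/35,
#'   or factor with flat first) and the outcome; typically a stacked
#'   [compute_index_set()] result, optionally with a `sequence` column.
#' @param outcome Name of the outcome column.
#' @param sequence Optional sequence label to subset on.
#' @return An object of class `inclination_fit` with `print`, `summary`,
#'   `coef`, `residuals`, `fitted` and `plot` methods. Coefficients carry
#'   estimates, standard errors, degrees of freedom and p-values.
#' @examples
#' d <- expand.grid(subject = 1:4, inclination = c(0, 18, 35))
#' d$vt <- 100 - 0.5 * d$inclination + rnorm(12)
#' fit_inclination_model(d, "vt")
#' @export
fit_inclination_model <- function(table, outcome, sequence = NULL) {
  if (!is.null(sequence)) table <- table[table$sequence == sequence, , drop = FALSE]
  if (!outcome %in% names(table)) abort_invalid("outcome '%s' not found", outcome)
  d <- data.frame(y = table[[outcome]],
                  inclination = incl_factor(table$inclination),
                  subject = factor(table$subject))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$subject)) < 2) abort_invalid("need at least 2 subjects")
  if (nlevels(droplevels(d$inclination)) < 2) abort_invalid("need at least 2 inclination levels")
  fit <- tryCatch(
    nlme::lme(y ~ inclination, random = ~ 1 | subject, data = d,
              method = "REML"),
    error = function(e) NULL)
  degraded <- is.null(fit)
  if (degraded) {
    lmfit <- stats::lm(y ~ inclination, data = d)
    s <- summary(lmfit)$coefficients
    tab <- data.frame(estimate = s[, 1], se = s[, 2],
                      df = stats::df.residual(lmfit),
                      t = s[, 3], p = s[, 4])
    res <- stats::residuals(lmfit); fit_vals <- stats::fitted(lmfit)
    rv <- 0
  } else {
    s <- summary(fit)$tTable
    tab <- data.frame(estimate = s[, "Value"], se = s[, "Std.Error"],
                      df = s[, "DF"], t = s[, "t-value"], p = s[, "p-value"])
    res <- stats::residuals(fit, type = "pearson")
    fit_vals <- stats::fitted(fit)
    rv <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"])
  }
  rownames(tab) <- sub("^inclination", "", rownames(tab))
  structure(list(outcome = outcome, sequence = sequence,
                 coefficients = tab,
                 random_intercept_var = rv,
                 residuals = res, fitted = fit_vals,
                 n_obs = nrow(d),
                 n_subjects = nlevels(droplevels(d$subject)),
                 degraded = degraded,
                 model = if (degraded) NULL else fit),
            class = "inclination_fit")
}

# 0/18/35 (numeric or character) -> factor with flat as reference
incl_factor <- function(x) {
  if (is.factor(x)) return(x)
  lab <- ifelse(x %in% c(0, "0", "flat"), "flat", paste0(as.character(x), "deg"))
  factor(lab, levels = c("flat", sort(unique(lab[lab != "flat"]))))
}

#' @export
print.inclination_fit <- function(x, ...) {
  cat(sprintf("Random-intercept inclination model: %s%s (%d obs, %d subjects%s)\n",
              x$outcome,
              if (is.null(x$sequence)) "" else paste0(" [", x$sequence, "]"),
              x$n_obs, x$n_subjects,
              if (x$degraded) "; degraded to fixed-effects-only" else ""))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.inclination_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Random-intercept variance: %.4g\n", object$random_intercept_var))
  invisible(object)
}

#' @export
coef.inclination_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
residuals.inclination_fit <- function(object, ...) object$residuals

#' @export
fitted.inclination_fit <- function(object, ...) object$fitted

#' Standardized-residual diagnostic plot
#' @param x An `inclination_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.inclination_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals,
                 xlab = "fitted values", ylab = "standardized residuals",
                 main = sprintf("%s: residuals vs fitted", x$outcome), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Paired before/after-compression contrast
#'
#' Estimates the after-minus-before change of a quantity measured on the
#' same subjects, as the phase fixed effect of a random-intercept model
#' (subject as the random effect), with a two-sided p-value and 95%
#' confidence interval. Unpaired rows are dropped with a warning. On
#' degenerate input (zero residual variance) the estimate is still the
#' mean paired difference, with p = 1 when that difference is zero.
#'
#' @param values_before,values_after Numeric vectors, one value per subject.
#' @param subjects Subject identifiers aligning the two vectors.
#' @return An object of class `cc_contrast`: `estimate`, `se`, `ci`
#'   (length-2), `p`, `n_pairs`, `method`.
#' @export
paired_cc_contrast <- function(values_before, values_after, subjects) {
  if (length(values_before) != length(subjects) ||
      length(values_after) != length(subjects)) {
    abort_invalid("before/after/subject lengths differ")
  }
  ok <- !is.na(values_before) & !is.na(values_after)
  if (any(!ok)) {
    warn_eitcpr("dropping %d unpaired/missing row(s)", sum(!ok),
                class = "eitcpr_unpaired")
  }
  b <- values_before[ok]; a <- values_after[ok]; s <- subjects[ok]
  n <- length(b)
  if (n < 1) abort_invalid("no complete pairs")
  diffs <- a - b
  scale <- mean(abs(c(a, b))) + 1
  degenerate <- n < 2 || stats::sd(diffs) < 1e-10 * scale
  if (degenerate) {
    est <- mean(diffs)
    p <- if (abs(est) < 1e-10 * scale) 1 else 0
    return(structure(list(estimate = est, se = 0, ci = c(est, est), p = p,
                          n_pairs = n,
                          method = "paired differences (degenerate variance)"),
                     class = "cc_contrast"))
  }
  d <- data.frame(value = c(b, a),
                  phase = factor(rep(c("before", "after"), each = n),
                                 levels = c("before", "after")),
                  subject = factor(rep(s, 2)))
  fit <- if (n >= 2) tryCatch(
    nlme::lme(value ~ phase, random = ~ 1 | subject, data = d, method = "REML"),
    error = function(e) NULL) else NULL
  if (!is.null(fit)) {
    s2 <- summary(fit)$tTable["phaseafter", ]
    est <- unname(s2["Value"]); se <- unname(s2["Std.Error"])
    df <- unname(s2["DF"]); p <- unname(s2["p-value"])
    method <- "random-intercept mixed model"
  } else {
    # degenerate fallback: one-sample t on the paired differences
    est <- mean(diffs); se <- stats::sd(diffs) / sqrt(n); df <- n - 1
    if (!is.finite(se) || se == 0) {
      p <- if (abs(est) < .Machine$double.eps^0.5 * (1 + abs(mean(b)))) 1 else 0
      se <- 0
    } else {
      p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
    }
    method <- "paired t on subject differences (degenerate variance)"
  }
  ci <- if (se > 0) est + c(-1, 1) * stats::qt(0.975, max(df, 1)) * se else c(est, est)
  structure(list(estimate = est, se = se, ci = ci, p = p,
                 n_pairs = n, method = method),
            class = "cc_contrast")
}

#' @export
print.cc_contrast <- function(x, ...) {
  cat(sprintf("After-vs-before contrast: %+.3f [%.3f, %.3f], p = %.4g (%d pairs; %s)\n",
              x$estimate, x$ci[1], x$ci[2], x$p, x$n_pairs, x$method))
  invisible(x)
}

#' Median and interquartile range
#'
#' Median with 1st and 3rd quartiles by the linear-interpolation convention
#' (R quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @param na.rm Drop missing values.
#' @return Named numeric vector `(median, q1, q3)`.
#' @examples
#' median_iqr(1:7)  # 4, 2.5, 5.5
#' @export
median_iqr <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (!length(values)) abort_invalid("empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
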
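test_that("inclination model matches group-mean differences on balanced data", {
  set.seed(10)
  d <- expand.grid(subject = 1:6, inclination = c(0, 18, 35))
  d$y <- 100 + 5 * (d$subject %% 3) - 0.8 * (d$inclination == 35) * 10 +
    stats::rnorm(nrow(d), 0, 0.5)
  ft <- fit_inclination_model(d, "y")
  gm <- tapply(d$y, d$inclination, mean)
  expect_equal(unname(coef(ft)["18deg"]), unname(gm["18"] - gm["0"]), tolerance = 1e-6)
  expect_equal(unname(coef(ft)["35deg"]), unname(gm["35"] - gm["0"]), tolerance = 1e-6)
  expect_false(ft$degraded)
  expect_equal(ft$n_subjects, 6)
  expect_true(all(ft$coefficients$p >= 0 & ft$coefficients$p <= 1))
  expect_equal(length(residuals(ft)), nrow(d))
})

test_that("identical groups give a zero contrast via the degraded path", {
  d <- expand.grid(subject = 1:4, inclination = c(0, 18, 35))
  d$y <- 10 * d$subject            # no inclination effect, zero residual
  ft <- fit_inclination_model(d, "y")
  expect_equal(unname(coef(ft)["35deg"]), 0)
  expect_equal(unname(coef(ft)["18deg"]), 0)
  expect_error(fit_inclination_model(d[d$subject == 1, ], "y"),
               class = "eitcpr_invalid_argument")
  expect_error(fit_inclination_model(d[d$inclination == 0, ], "y"),
               class = "eitcpr_invalid_argument")
})

test_that("paired contrast recovers constant shifts and degenerate cases", {
  set.seed(11)
  b <- stats::rnorm(7, -0.3, 0.1)
  a <- b - 0.8 + stats::rnorm(7, 0, 0.01)
  ct <- paired_cc_contrast(b, a, paste0("c", 1:7))
  expect_equal(ct$estimate, -0.8, tolerance = 0.05)
  expect_lt(ct$p, 0.001)
  # identical pairs: p = 1
  ct0 <- paired_cc_contrast(b, b, paste0("c", 1:7))
  expect_equal(ct0$estimate, 0, tolerance = 1e-12)
  expect_equal(ct0$p, 1, tolerance = 1e-6)
  # sign of the estimate follows the injected direction across seeds
  for (seed in 1:5) {
    set.seed(seed)
    bb <- stats::rnorm(7); shift <- sample(c(-1, 1), 1) * 0.6
    aa <- bb + shift + stats::rnorm(7, 0, 0.05)
    expect_equal(sign(paired_cc_contrast(bb, aa, 1:7)$estimate), sign(shift))
  }
  expect_warning(paired_cc_contrast(c(1, NA, 3), c(1, 2, 3), 1:3),
                 class = "eitcpr_unpaired")
})

test_that("type-I error of the 35-deg contrast is calibrated under the null", {
  set.seed(2024)
  n_rep <- 500
  rejections <- 0L
  d0 <- expand.grid(subject = 1:7, inclination = c(0, 18, 35))
  for (r in seq_len(n_rep)) {
    d0$y <- stats::rnorm(7, sd = 1)[d0$subject] + stats::rnorm(nrow(d0), sd = 0.5)
    ft <- fit_inclination_model(d0, "y")
    if (ft$coefficients["35deg", "p"] < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("median and quartiles follow the linear-interpolation convention", {
  expect_equal(median_iqr(1:7), c(median = 4, q1 = 2.5, q3 = 5.5))
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(median_iqr(x), median_iqr(sort(x)))   # permutation-invariant
  expect_error(median_iqr(numeric(0)), class = "eitcpr_invalid_argument")
})
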
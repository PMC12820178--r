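test_that("predictor standardisation is exact and errors on constants", {
  set.seed(1)
  v <- rnorm(50, 10, 3)
  z <- standardize_predictor(v)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(attr(z, "center"), mean(v))
  expect_error(standardize_predictor(rep(2, 10)), "zero SD")
})

test_that("per-SD odds ratio is the per-unit OR raised to the SD power", {
  set.seed(2)
  n <- 3000
  x <- rnorm(n, 0, 2.5)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * x))
  f_unit <- fit_logistic(y, x, standardize_exposure = FALSE)
  f_sd <- fit_logistic(y, x)
  b_unit <- f_unit$coefficients$estimate[f_unit$coefficients$term == "exposure"]
  b_sd <- f_sd$coefficients$estimate[f_sd$coefficients$term == "exposure"]
  expect_equal(exp(b_sd), exp(b_unit)^sd(x), tolerance = 1e-6)
})

test_that("logistic MLE reproduces the closed-form 2x2 odds ratio", {
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(y, x, standardize_exposure = FALSE)
  cf <- fit$coefficients[fit$coefficients$term == "exposure", ]
  expect_equal(cf$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
})

test_that("logistic MLE agrees with direct likelihood maximisation", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 150
    X <- cbind(rnorm(n), rnorm(n))
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * X[, 1] - 0.4 * X[, 2]))
    fit <- fit_logistic(y, X[, 1], data.frame(c2 = X[, 2]),
                        standardize_exposure = FALSE)
    nll <- function(b) -sum(y * (b[1] + b[2] * X[, 1] + b[3] * X[, 2]) -
                              log1p(exp(b[1] + b[2] * X[, 1] + b[3] * X[, 2])))
    opt <- optim(c(0, 0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(fit$coefficients$estimate), unname(opt$par),
                 tolerance = 1e-5)
  }
})

test_that("degenerate designs are refused with informative errors", {
  set.seed(4)
  n <- 200
  bmi <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + bmi))
  expect_error(adjusted_score_model(y, bmi, bmi), "aliased")
  # complete separation
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- rep(c(0, 1), each = 50)
  expect_error(fit_logistic(ys, xs), "separation|converge")
  expect_error(fit_logistic(rep(1, 50), rnorm(50)), "single class")
})

test_that("null exposures give nominal Wald CI coverage of OR = 1", {
  set.seed(5)
  cover <- vapply(1:50, function(i) {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.2)
    cf <- fit_logistic(y, x)$coefficients
    cf <- cf[cf$term == "exposure", ]
    cf$ci_low <= 1 && 1 <= cf$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("score conditional on BMI is null when it carries no extra signal", {
  set.seed(6)
  cover <- vapply(1:50, function(i) {
    n <- 1500
    bmi <- rnorm(n)
    score <- 0.7 * bmi + rnorm(n, 0, sqrt(1 - 0.49))
    y <- rbinom(n, 1, plogis(-1.2 + 0.5 * bmi))  # outcome depends on BMI only
    cf <- adjusted_score_model(y, score, bmi)$coefficients
    cf <- cf[cf$term == "score", ]
    cf$ci_low <= 1 && 1 <= cf$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("likelihood ratio test handles identity, nesting and recoding", {
  set.seed(7)
  n <- 400
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  red <- fit_logistic(y, x, exposure_name = "x")
  full <- fit_logistic(y, x, data.frame(z = z), exposure_name = "x")
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  # identical models: statistic 0, p = 1
  same <- likelihood_ratio_test(red, red)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # non-nested inputs are refused
  other <- fit_logistic(y, z, exposure_name = "w")
  expect_error(likelihood_ratio_test(full, other), "nested")
  # affine recoding of the shared covariate leaves the statistic unchanged
  red2 <- fit_logistic(y, 10 + 3 * x, exposure_name = "x",
                       standardize_exposure = FALSE)
  full2 <- fit_logistic(y, 10 + 3 * x, data.frame(z = z), exposure_name = "x",
                        standardize_exposure = FALSE)
  lrt2 <- likelihood_ratio_test(full2, red2)
  expect_equal(lrt2$statistic, lrt$statistic, tolerance = 1e-6)
})

test_that("association table enumerates pairs and round-trips formatting", {
  set.seed(8)
  n <- 300
  outcomes <- as.data.frame(replicate(5, rbinom(n, 1, 0.3)))
  names(outcomes) <- paste0("y", 1:5)
  exposures <- list(bmi = rnorm(n), score = rnorm(n))
  tab <- association_table(outcomes, exposures)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$n == n))
  back <- parse_or(tab$pretty)
  expect_equal(back$or, as.numeric(sprintf("%.2f", tab$or)))
  expect_equal(back$ci_low, as.numeric(sprintf("%.2f", tab$ci_low)))
  expect_equal(parse_or("1.90 [1.29-2.74]"),
               data.frame(or = 1.9, ci_low = 1.29, ci_high = 2.74))
  expect_error(parse_or("garbage"), "unparseable")
})

test_that("social-circumstances PC1 summarises correlated inputs", {
  set.seed(9)
  n <- 200
  ses <- rnorm(n)
  df <- data.frame(income = ses + rnorm(n, 0, 0.5),
                   education = ses + rnorm(n, 0, 0.5),
                   age = 0.5 * ses + rnorm(n, 0, 0.8))
  pc <- first_pc_score(df)
  expect_lt(abs(mean(pc)), 1e-10)
  expect_gt(cor(pc, ses), 0.7)
  expect_gt(cor(pc, df$income), 0)   # orientation anchored to first column
})
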
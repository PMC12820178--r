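test_that("missingness filter excludes strictly above the threshold", {
  set.seed(1)
  n <- 100
  fr <- c(0, 0.20, 0.33, 0.34, 0.50)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  for (j in seq_along(fr)) x[seq_len(round(fr[j] * n)), j] <- NA
  res <- filter_by_missingness(x, 1 / 3)
  expect_identical(colnames(res$matrix), c("m1", "m2", "m3"))
  expect_equal(res$report$n_excluded_missingness, 2)
  expect_equal(unname(res$report$missing_frac), fr)  # planted fractions exact
  # fully observed matrix passes through untouched
  y <- matrix(rnorm(20), 5, 4)
  res2 <- filter_by_missingness(y)
  expect_identical(res2$matrix, y)
  expect_equal(res2$report$n_excluded_missingness, 0)
  # all-excluded is an error, not an empty matrix
  z <- matrix(c(NA, NA, NA, 1), 4, 1)
  expect_error(filter_by_missingness(z, 0.5), "threshold")
})

test_that("RF imputation preserves observed cells and handles edge cases", {
  set.seed(2)
  x <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("m", 1:6)))
  expect_identical(rf_impute(x)$matrix, x)          # complete -> identity
  xc <- x; xc[, 2] <- 5; xc[7, 2] <- NA             # constant column
  expect_equal(unname(rf_impute(xc, seed = 1)$matrix[7, 2]), 5)
  xa <- x; xa[, 3] <- NA
  expect_error(rf_impute(xa), "m3")                 # all-missing named
  xm <- x; xm[sample(300, 40)] <- NA
  imp <- rf_impute(xm, seed = 3)$matrix
  expect_identical(imp[!is.na(xm)], xm[!is.na(xm)]) # observed untouched
  expect_false(anyNA(imp))
})

test_that("one-iteration RF imputation equals an explicit single sweep", {
  set.seed(4)
  A <- rnorm(80)
  x <- cbind(m1 = A + rnorm(80, 0, 0.3), m2 = A + rnorm(80, 0, 0.3),
             m3 = rnorm(80))
  x[sample(240, 30)] <- NA
  got <- rf_impute(x, seed = 99, max_iter = 1L)$matrix
  want <- rf_one_sweep(x, seed = 99)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("RF imputation beats column-mean imputation on correlated data", {
  set.seed(5)
  n <- 150
  A <- rnorm(n)
  truth <- cbind(m1 = A + rnorm(n, 0, sqrt(1 - 0.95^2) / 0.95),
                 m2 = A + rnorm(n, 0, sqrt(1 - 0.95^2) / 0.95),
                 m3 = rnorm(n), m4 = rnorm(n))
  mask <- matrix(runif(n * 4) < 0.10, n, 4)
  x <- truth; x[mask] <- NA
  rf <- rf_impute(x, seed = 6)$matrix
  mi <- mean_impute(x)
  expect_lt(masked_rmse(rf, truth, mask), masked_rmse(mi, truth, mask))
})

test_that("log/centre/scale standardizes, is scale-invariant and monotone", {
  set.seed(7)
  x <- matrix(exp(rnorm(200)), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  res <- log_center_scale(x)
  expect_true(all(abs(colMeans(res$z)) < 1e-10))
  expect_true(all(abs(apply(res$z, 2, sd) - 1) < 1e-10))
  # multiplying a column by a positive constant leaves the output unchanged
  x2 <- x; x2[, 3] <- x2[, 3] * 17.5
  expect_equal(log_center_scale(x2)$z, res$z, tolerance = 1e-12)
  # ranks preserved within columns
  expect_identical(apply(res$z, 2, rank), apply(x, 2, rank))
  # errors: non-positive cell with coordinates, zero-variance column
  xb <- x; xb[3, 2] <- 0
  expect_error(log_center_scale(xb), "3, 2")
  xz <- x; xz[, 4] <- 2
  expect_error(log_center_scale(xz), "m4")
})

test_that("standardisation parameters transfer exactly", {
  set.seed(8)
  x <- matrix(exp(rnorm(300)), 60, 5, dimnames = list(NULL, paste0("m", 1:5)))
  res <- log_center_scale(x)
  # shuffled columns re-standardized through the stored parameters
  expect_equal(apply_standardization(x[, c(3, 1, 2, 5, 4)], res$params),
               res$z, tolerance = 1e-12)
  expect_error(apply_standardization(x[, 1:3], res$params), "m4")
})

test_that("twin de-duplication keeps one record per family, reproducibly", {
  cfg <- small_config(seed = 19, n_samples = 100L, twin_rate = 0.06)
  g <- generate_cohort(cfg)
  expect_equal(sum(duplicated(g$data$family_id)), 3)
  d1 <- dedupe_twins(g$data, seed = 5)
  expect_equal(nrow(d1$abundances), 97)
  expect_false(anyDuplicated(d1$family_id) > 0)
  expect_identical(dedupe_twins(g$data, seed = 5), d1)
  # no duplicates -> identity
  expect_identical(dedupe_twins(d1, seed = 5), d1)
})

test_that("missingness-outcome diagnostic recovers a planted mechanism", {
  cfg <- cohort_config(n_samples = 2000L, n_metabolites = 60L, n_signal = 0L,
                       n_mediators = 0L, twin_rate = 0, missing_rate = 0.15,
                       missing_mechanism = "outcome_dependent",
                       missing_outcome = "y", missing_gamma = -0.5,
                       outcome_specs = list(outcome_spec("y", 0.3)),
                       seed = 23)
  g <- generate_cohort(cfg)
  d <- apply_missingness(g$data, cfg)
  sub <- colnames(d$mask)[1:20]
  fit <- missingness_outcome_association(d$mask, d$outcomes$y, sub,
                                         predictor = "count")
  cf <- fit$coefficients[fit$coefficients$term == "missing_count", ]
  expect_lt(cf$or, 1)
  expect_lt(cf$p, 0.05)
  # constant predictor is refused
  clean <- matrix(FALSE, 100, 5, dimnames = list(NULL, paste0("m", 1:5)))
  expect_error(missingness_outcome_association(clean, rbinom(100, 1, 0.3),
                                               "m1"), "constant")
  expect_error(missingness_outcome_association(d$mask, d$outcomes$y,
                                               character(0)), "non-empty")
})

test_that("PCA covariate imputation recovers rank-1 structure and beats means", {
  # exact rank-1 table with one masked cell is recovered almost exactly
  u <- c(1, 2, 3, 4, 5, 6); v <- c(2, -1, 0.5)
  tab <- as.data.frame(u %*% t(v))
  names(tab) <- c("a", "b", "c")
  holed <- tab; holed[3, 2] <- NA
  imp <- pca_impute_covariates(holed, n_components = 1L)
  expect_lt(abs(imp[3, 2] - tab[3, 2]), 1e-4)
  # complete table is the identity
  expect_identical(pca_impute_covariates(tab), tab)

  # correlated numeric columns: masked-truth error below mean imputation
  set.seed(10)
  n <- 200
  f <- rnorm(n)
  truth <- data.frame(x1 = f + rnorm(n, 0, 0.3), x2 = f + rnorm(n, 0, 0.3),
                      x3 = -f + rnorm(n, 0, 0.3))
  mask <- matrix(runif(n * 3) < 0.10, n, 3)
  holed <- truth; holed[mask] <- NA
  imp <- pca_impute_covariates(holed)
  tm <- as.matrix(truth)
  err_pca <- sqrt(mean((as.matrix(imp)[mask] - tm[mask])^2))
  mi <- as.matrix(holed)
  cm <- colMeans(mi, na.rm = TRUE)
  for (j in 1:3) mi[is.na(mi[, j]), j] <- cm[j]
  err_mean <- sqrt(mean((mi[mask] - tm[mask])^2))
  expect_lt(err_pca, err_mean)
  # observed cells never altered
  expect_equal(as.matrix(imp)[!mask], tm[!mask])
})

test_that("PCA imputation fills categorical covariates from their level set", {
  set.seed(11)
  n <- 120
  f <- rnorm(n)
  cov <- data.frame(x = f, y = 2 * f + rnorm(n, 0, 0.2),
                    g = factor(ifelse(f > 0, "hi", "lo")))
  holed <- cov
  holed$g[sample(n, 12)] <- NA
  holed$x[sample(n, 12)] <- NA
  imp <- pca_impute_covariates(holed)
  expect_false(anyNA(imp))
  expect_true(all(imp$g %in% c("hi", "lo")))
  # imputed categories mostly agree with truth (signal is strong)
  na_g <- which(is.na(holed$g))
  expect_gt(mean(imp$g[na_g] == cov$g[na_g]), 0.7)
})
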
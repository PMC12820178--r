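# shared fixture: standardized metabolite matrix with a latent-factor BMI
# signal and a mediated binary outcome
make_mediation_data <- function(n = 1500, p = 10, k_med = 3, seed = 1,
                                a = 0.6, b = 0.5) {
  set.seed(seed)
  A <- rnorm(n)
  Z <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("M%02d", seq_len(p))))
  Z <- Z + outer(A, rep(0.7, p))          # all columns load on adiposity
  Z <- scale(Z)
  bmi <- a * A + sqrt(1 - a^2) * rnorm(n)
  med <- seq_len(k_med)
  lp <- qlogis(0.2) + b * rowSums(Z[, med, drop = FALSE]) / sqrt(k_med)
  y <- rbinom(n, 1, plogis(lp))
  list(Z = Z, bmi = bmi, y = y,
       model = manual_spls_model(colnames(Z),
                                 setNames(rep(1 / sqrt(p), p), colnames(Z))),
       mediators = colnames(Z)[med])
}

test_that("composite score restriction, sign and variance behave", {
  set.seed(2)
  Z <- scale(matrix(rnorm(200 * 6), 200, 6,
                    dimnames = list(NULL, paste0("M", 1:6))))
  w <- setNames(c(0.5, -0.3, 0.2, 0.4, 0.1, -0.2), colnames(Z))
  model <- manual_spls_model(colnames(Z), w)
  s_all <- composite_score(Z, model, colnames(Z))
  expect_equal(as.numeric(s_all),
               as.numeric(scale(Z %*% w)), tolerance = 1e-12)
  # singleton subset is the (sign-carrying) z-scored metabolite
  s1 <- composite_score(Z, model, "M2")
  expect_equal(as.numeric(s1), as.numeric(scale(-Z[, "M2"])), tolerance = 1e-12)
  # orthogonal columns: raw variance of union = sum of part variances
  raw_a <- attr(composite_score(Z, model, c("M1", "M2")), "raw")
  raw_b <- attr(composite_score(Z, model, c("M3", "M4")), "raw")
  raw_u <- attr(composite_score(Z, model, c("M1", "M2", "M3", "M4")), "raw")
  expect_equal(var(raw_u), var(raw_a) + var(raw_b) + 2 * cov(raw_a, raw_b),
               tolerance = 1e-12)
  expect_error(composite_score(Z, model, character(0)), "empty")
  expect_error(composite_score(Z, model, "M9"), "M9")
})

test_that("ACME + ADE equals the total effect draw by draw and runs reproduce", {
  d <- make_mediation_data(n = 600, seed = 3)
  r1 <- mediate_composite(d$Z, d$bmi, d$y, model = d$model, n_sim = 300,
                          seed = 5, keep_draws = TRUE)
  expect_true(all(abs(r1$draws$acme + r1$draws$ade - r1$draws$total) < 1e-12))
  expect_true(r1$acme_ci[1] <= r1$acme && r1$acme <= r1$acme_ci[2])
  expect_equal(r1$total, r1$acme + r1$ade, tolerance = 1e-12)
  r2 <- mediate_composite(d$Z, d$bmi, d$y, model = d$model, n_sim = 300,
                          seed = 5, keep_draws = TRUE)
  expect_identical(r1, r2)
})

test_that("a severed exposure-mediator path yields a null ACME", {
  set.seed(4)
  n <- 2000
  Z <- scale(matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("M", 1:4))))
  bmi <- rnorm(n)                        # independent of the metabolites
  y <- rbinom(n, 1, plogis(-1 + 0.3 * rowMeans(Z)))
  model <- manual_spls_model(colnames(Z),
                             setNames(rep(0.5, 4), colnames(Z)))
  res <- mediate_composite(Z, bmi, y, model = model, n_sim = 2000, seed = 6)
  expect_lt(abs(res$acme), 0.01)
  expect_true(res$acme_ci[1] <= 0 && 0 <= res$acme_ci[2])
})

test_that("linear-linear mediation recovers the product of coefficients", {
  set.seed(5)
  n <- 4000
  a <- 0.5; b <- 0.4
  x <- rnorm(n)
  m <- a * x + rnorm(n)
  y <- b * m + 0.3 * x + rnorm(n)
  med_fit <- lm(m ~ x)
  out_fit <- lm(y ~ x + m)
  res <- acme_quasi_bayes(med_fit, out_fit, exposure = "x",
                          treat = 1, control = 0, n_sim = 2000, seed = 7)
  expect_lt(abs(res$acme - a * b), 0.03)
  expect_lt(abs(res$ade - 0.3), 0.03)
  expect_lt(abs(res$prop_mediated - a * b / (a * b + 0.3)), 0.1)
})

test_that("input validation catches broken mediation setups", {
  d <- make_mediation_data(n = 300, seed = 8)
  s <- as.numeric(composite_score(d$Z, d$model))
  df <- data.frame(y = d$y, bmi = d$bmi, score = s)
  med_fit <- lm(score ~ bmi, data = df)
  out_no_med <- glm(y ~ bmi, data = df, family = binomial())
  expect_error(acme_quasi_bayes(med_fit, out_no_med), "mediator")
  out_fit <- glm(y ~ bmi + score, data = df, family = binomial())
  med_const <- lm(I(score * 0) ~ bmi, data = df)
  expect_error(acme_quasi_bayes(med_const, out_fit), "residual variance")
  expect_error(acme_quasi_bayes(med_fit, out_fit, n_sim = 10), "n_sim")
})

test_that("a model at min_size yields a trace with no removals", {
  d <- make_mediation_data(n = 400, p = 2, k_med = 1, seed = 9)
  trace <- backward_eliminate(d$Z, d$bmi, d$y, model = d$model,
                              n_sim = 200, seed = 1, min_size = 2)
  expect_equal(nrow(trace$steps), 0)
  expect_equal(trace$stopping_reason, "min_size")
  expect_identical(trace$final_set, trace$initial_set)
})

test_that("elimination trace ACME is strictly increasing and reproducible", {
  d <- make_mediation_data(n = 800, p = 6, k_med = 2, seed = 10)
  t1 <- backward_eliminate(d$Z, d$bmi, d$y, model = d$model,
                           n_sim = 300, seed = 11, min_size = 2)
  acmes <- c(t1$initial$acme, t1$steps$acme)
  if (length(acmes) > 1) expect_true(all(diff(acmes) > 0))
  expect_true(all(t1$steps$removed_id %in% t1$initial_set))
  expect_gte(length(t1$final_set), 2)
  t2 <- backward_eliminate(d$Z, d$bmi, d$y, model = d$model,
                           n_sim = 300, seed = 11, min_size = 2)
  expect_identical(t1, t2)
})

test_that("with no metabolite-outcome effects the final ACME stays null", {
  set.seed(12)
  n <- 1200
  Z <- scale(matrix(rnorm(n * 5) + 0.6 * rnorm(n), n, 5,
                    dimnames = list(NULL, paste0("M", 1:5))))
  bmi <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * bmi))   # direct effect only
  model <- manual_spls_model(colnames(Z), setNames(rep(0.45, 5), colnames(Z)))
  trace <- backward_eliminate(Z, bmi, y, model = model, n_sim = 300,
                              seed = 13, min_size = 2)
  expect_true(trace$final$acme_ci[1] <= 0 && 0 <= trace$final$acme_ci[2])
})

test_that("subset-score comparison detects added signal and rejects collinearity", {
  d <- make_mediation_data(n = 2500, p = 10, k_med = 3, seed = 14, b = 0.8)
  full_score <- as.numeric(composite_score(d$Z, d$model))
  subset_score <- as.numeric(composite_score(d$Z, d$model, d$mediators))
  cmp <- compare_full_vs_subset(d$y, full_score, subset_score, d$bmi)
  expect_equal(cmp$lrt$df, 1)
  expect_lt(cmp$lrt$p, 0.05)     # concentrated subset beats the diluted score
  expect_error(compare_full_vs_subset(d$y, full_score, full_score, d$bmi),
               "aliased")
})
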
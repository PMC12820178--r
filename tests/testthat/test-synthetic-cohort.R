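test_that("config validation names the offending field", {
  expect_error(cohort_config(n_signal = 50, n_metabolites = 40), "n_signal")
  expect_error(cohort_config(n_mediators = 20, n_signal = 10), "n_mediators")
  expect_error(cohort_config(signal_r2 = 1), "signal_r2")
  expect_error(cohort_config(missing_rate = 0.7), "missing_rate")
  expect_error(cohort_config(outcome_specs = list(outcome_spec("y", 0))),
               "prevalence")
  expect_error(cohort_config(missing_mechanism = "outcome_dependent",
                             missing_outcome = "nonexistent"),
               "missing_outcome")
})

test_that("fixed seed reproduces the cohort byte for byte", {
  cfg <- small_config(seed = 11)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  # and a different seed changes it
  g3 <- generate_cohort(cfg, seed = 12)
  expect_false(identical(g1$data$abundances, g3$data$abundances))
})

test_that("truth record obeys its invariants", {
  g <- generate_cohort(small_config(seed = 3))
  tr <- g$truth
  expect_true(all(tr$mediator_ids %in% tr$signal_ids))
  non_signal <- setdiff(names(tr$true_weights), tr$signal_ids)
  expect_true(all(tr$true_weights[non_signal] == 0))
  expect_true(all(tr$true_weights[tr$signal_ids] != 0))
  # mediators have nonzero weight x outcome coefficient product
  oc <- tr$true_outcome_coefs$gestational_diabetes
  prod <- tr$true_weights[tr$mediator_ids] * oc$mediator_logors[tr$mediator_ids]
  expect_true(all(prod != 0))
  expect_true(all(g$data$abundances > 0))
  expect_true(all(unlist(g$data$outcomes) %in% 0:1))
})

test_that("zero-effect outcome prevalence matches its target", {
  cfg <- null_config(seed = 5, n_samples = 5000L, prevalence = 0.20)
  g <- generate_cohort(cfg)
  phat <- mean(g$data$outcomes$y)
  tol <- 3 * sqrt(0.2 * 0.8 / 5000)
  expect_lt(abs(phat - 0.20), tol)
})

test_that("BMI variance explained by the true-weight composite matches signal_r2", {
  cfg <- small_config(seed = 21, n_samples = 5000L, n_metabolites = 80L,
                      n_signal = 40L, n_mediators = 5L, missing_rate = 0,
                      twin_rate = 0, signal_r2 = 0.4)
  g <- generate_cohort(cfg)
  Z <- std_log_abund(g$data)
  comp <- drop(Z[, g$truth$signal_ids] %*% g$truth$true_weights[g$truth$signal_ids])
  r2 <- summary(lm(g$data$bmi ~ comp))$r.squared
  expect_lt(abs(r2 - 0.4), 0.05)
})

test_that("twin pairs duplicate family ids with tightly correlated BMI", {
  cfg <- small_config(seed = 9, n_samples = 500L, twin_rate = 0.1)
  g <- generate_cohort(cfg)
  fam <- table(g$data$family_id)
  expect_equal(sum(fam == 2), round(0.1 * 500 / 2))
  pairs <- names(fam)[fam == 2]
  idx <- lapply(pairs, function(f) which(g$data$family_id == f))
  b1 <- vapply(idx, function(i) g$data$bmi[i[1]], numeric(1))
  b2 <- vapply(idx, function(i) g$data$bmi[i[2]], numeric(1))
  expect_gt(cor(b1, b2), 0.9)
})

test_that("MCAR missingness hits its rate and zero rate is the identity", {
  cfg <- small_config(seed = 13, n_samples = 500L, n_metabolites = 100L,
                      missing_rate = 0.2)
  g <- generate_cohort(cfg)
  expect_identical(apply_missingness(g$data,
                                     small_config(seed = 13, missing_rate = 0)),
                   g$data)
  d <- apply_missingness(g$data, cfg)
  frac <- mean(d$mask)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / (500 * 100)))
  expect_identical(is.na(d$abundances), d$mask)
  # re-applying on an already-masked cohort is refused
  expect_error(apply_missingness(d, cfg), "all-observed")
})

test_that("outcome-dependent missingness induces the planted association", {
  cfg <- cohort_config(n_samples = 2000L, n_metabolites = 100L,
                       n_signal = 0L, n_mediators = 0L, twin_rate = 0,
                       missing_rate = 0.25,
                       missing_mechanism = "outcome_dependent",
                       missing_outcome = "y", missing_gamma = -0.5,
                       outcome_specs = list(outcome_spec("y", 0.3)),
                       seed = 31)
  g <- generate_cohort(cfg)
  d <- apply_missingness(g$data, cfg)
  n_missing <- rowSums(d$mask)
  fit <- glm(cbind(n_missing, 100 - n_missing) ~ d$outcomes$y,
             family = binomial())
  expect_lt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 0.05)
})

test_that("covariate missingness injection is MCAR and type-safe", {
  g <- generate_cohort(small_config(seed = 17, n_samples = 1000L))
  cov <- g$data$covariates[, 1:5]
  expect_identical(inject_covariate_missingness(cov, 0), cov)
  holed <- inject_covariate_missingness(cov, 0.1, seed = 2)
  n_na <- sum(is.na(holed))
  expect_lt(abs(n_na - 500), 60)
  expect_true(all(levels(holed$child_sex) %in% levels(cov$child_sex)))
  expect_error(inject_covariate_missingness(cov, 0.5), "rate")
})
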
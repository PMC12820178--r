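# Small cohort configurations used across the suite.  Outcome prevalences at
# desk scale are kept >= 0.15 so logistic fits stay well conditioned at
# n ~ 200.

small_config <- function(seed = 7, n_samples = 200L, n_metabolites = 120L,
                         n_signal = 15L, n_mediators = 5L,
                         missing_rate = 0.05, ...) {
  cohort_config(
    n_samples = n_samples, n_metabolites = n_metabolites,
    n_signal = n_signal, n_mediators = n_mediators,
    missing_rate = missing_rate, seed = seed,
    outcome_specs = list(
      outcome_spec("gestational_diabetes", 0.15, bmi_logor = 0.2,
                   mediator_logor = 0.3),
      outcome_spec("cesarean_section", 0.25, bmi_logor = 0.2)),
    ...)
}

# config with every effect switched off (null world)
null_config <- function(seed = 7, n_samples = 1000L, n_metabolites = 30L,
                        prevalence = 0.2, ...) {
  cohort_config(
    n_samples = n_samples, n_metabolites = n_metabolites,
    n_signal = 0L, n_mediators = 0L, signal_r2 = 0.3,
    missing_rate = 0, twin_rate = 0, seed = seed,
    outcome_specs = list(outcome_spec("y", prevalence)),
    covariate_specs = list(bmi_effects = c(social_circumstances = 0),
                           outcome_effects = c(social_circumstances = 0)),
    ...)
}

# standardized matrix of log-abundances (complete cohorts only)
std_log_abund <- function(data) {
  log_center_scale(data$abundances, log = TRUE)$z
}

# simulate (Z, y) with `k` informative columns among `p`, latent-factor
# structure matching the generator: signal columns = w * A + noise,
# y = sqrt(r2) * A + noise
planted_zy <- function(n, p, k, r2 = 0.4, w_range = c(0.5, 1)) {
  A <- rnorm(n)
  Z <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("M%03d", seq_len(p))))
  w <- runif(k, w_range[1], w_range[2])
  Z[, seq_len(k)] <- Z[, seq_len(k)] + outer(A, w)
  y <- sqrt(r2) * A + sqrt(1 - r2) * rnorm(n)
  list(Z = Z, y = y, signal = colnames(Z)[seq_len(k)])
}

# hand-built sPLS model over given ids with given weights
manual_spls_model <- function(ids, weights, eta = 0) {
  w <- numeric(length(ids)); names(w) <- ids
  w[names(weights)] <- weights
  structure(list(weights = w, eta = eta, training_column_ids = ids,
                 intercept = 0, slope = 1, r2_insample = NA_real_,
                 rmsecv = NA_real_, r2cv = NA_real_, tuning = NULL,
                 training_standardisation = NULL,
                 response_center_scale = NULL),
            class = "spls_model")
}
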
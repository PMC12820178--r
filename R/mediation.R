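## Quasi-Bayesian causal mediation and backward elimination
##
## The mediator is a composite metabolite score (fixed sPLS weights
## restricted to a subset, re-standardized), the exposure is standardized
## BMI, and the outcome is a binary complication.  The average causal
## mediation effect (ACME) is estimated on the probability (risk-difference)
## scale by simulating model parameters from their asymptotic normal
## sampling distributions, generating counterfactual mediator values at the
## treated and control exposure, pushing them through the outcome model, and
## averaging over samples and the two exposure arms.  Backward elimination
## repeatedly drops the metabolite whose removal most increases the ACME.

#' Composite metabolite score over a subset
#'
#' Weighted sum of standardized metabolites using the sPLS model's weights
#' restricted to `subset`, then z-scored.
#'
#' @param Z standardized samples x metabolites matrix containing the subset
#'   columns.
#' @param model an `spls_model`.
#' @param subset non-empty character vector of metabolite ids within the
#'   model.
#' @return z-scored composite score; the raw weighted sum is in attribute
#'   `"raw"`.
#' @export
composite_score <- function(Z, model, subset = selected_metabolites(model)) {
  stopifnot(inherits(model, "spls_model"), is.matrix(Z))
  if (length(subset) == 0L) stop("`subset` is empty", call. = FALSE)
  bad <- setdiff(subset, names(model$weights))
  if (length(bad))
    stop(sprintf("subset id(s) not in the model: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(subset, colnames(Z))
  if (length(bad))
    stop(sprintf("subset id(s) not in the matrix: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  raw <- drop(Z[, subset, drop = FALSE] %*% model$weights[subset])
  structure(zscore(raw, "composite score"), raw = raw)
}

#' Quasi-Bayesian average causal mediation effect (binary outcome)
#'
#' Given a linear mediator model (`score ~ exposure + covariates`) and a
#' logistic outcome model (`outcome ~ exposure + score + covariates`) fitted
#' on the same samples, draws `n_sim` coefficient vectors from each model's
#' asymptotic normal distribution; per draw, simulates counterfactual
#' mediator values at `exposure = treat` and `exposure = control` (adding
#' mediator-model residual noise, shared between arms as common random
#' numbers), converts the four exposure/mediator combinations to predicted
#' outcome probabilities, and averages over samples.  ACME is the mean over
#' the two exposure arms of `E[Y(a, M(treat))] - E[Y(a, M(control))]`; ADE
#' is the analogous exposure contrast at fixed mediator arm; their sum is
#' the total effect draw by draw.
#'
#' @param mediator_fit `lm` of the composite score on the exposure and
#'   covariates.
#' @param outcome_fit `glm(binomial)` of the outcome on exposure, score and
#'   covariates; an `lm` (identity link) is also accepted, in which case all
#'   effects are on the outcome's own scale and the ACME reduces to the
#'   product of coefficients in large samples.
#' @param exposure name of the exposure variable in both models.
#' @param treat,control exposure values contrasted; default mean and mean +
#'   1 SD of the observed exposure (per-SD contrast).
#' @param n_sim number of parameter draws (>= 100; 10,000 for final
#'   inference).
#' @param seed integer seed.
#' @param keep_draws retain per-draw ACME/ADE/total vectors.
#' @return a `mediation_result`: `acme`, `ade`, `total`, `prop_mediated`
#'   (reported only when ACME and total share a sign), percentile intervals
#'   `*_ci`, `n_sim`, `seed`, and optionally `draws`.
#' @export
acme_quasi_bayes <- function(mediator_fit, outcome_fit, exposure = "bmi",
                             treat = NULL, control = NULL, n_sim = 10000L,
                             seed = NULL, keep_draws = FALSE) {
  stopifnot(inherits(mediator_fit, "lm"), inherits(outcome_fit, "lm"))
  n_sim <- check_count(n_sim, "n_sim", min = 100L)
  is_glm <- inherits(outcome_fit, "glm")
  if (is_glm && !outcome_fit$converged)
    stop("outcome model did not converge", call. = FALSE)
  linkinv <- if (is_glm) outcome_fit$family$linkinv else identity
  med_name <- all.vars(stats::formula(mediator_fit))[1]
  Xm <- stats::model.matrix(mediator_fit)
  Xo <- stats::model.matrix(outcome_fit)
  if (!exposure %in% colnames(Xm) || !exposure %in% colnames(Xo))
    stop(sprintf("exposure `%s` must appear in both model designs", exposure),
         call. = FALSE)
  if (!med_name %in% colnames(Xo))
    stop(sprintf("mediator `%s` must appear in the outcome design", med_name),
         call. = FALSE)
  n <- nrow(Xm)
  if (nrow(Xo) != n)
    stop("mediator and outcome models use different samples", call. = FALSE)
  sigma <- summary(mediator_fit)$sigma
  if (!is.finite(sigma) || sigma < 1e-10)
    stop("degenerate mediator residual variance", call. = FALSE)
  e_obs <- Xm[, exposure]
  if (is.null(control)) control <- mean(e_obs)
  if (is.null(treat)) treat <- mean(e_obs) + stats::sd(e_obs)

  coef_m <- stats::coef(mediator_fit); vcov_m <- stats::vcov(mediator_fit)
  coef_o <- stats::coef(outcome_fit);  vcov_o <- stats::vcov(outcome_fit)
  exp_o <- match(exposure, colnames(Xo))
  med_o <- match(med_name, colnames(Xo))
  Xm_t <- Xm; Xm_t[, exposure] <- treat
  Xm_c <- Xm; Xm_c[, exposure] <- control
  Xo0 <- Xo; Xo0[, c(exp_o, med_o)] <- 0

  acme_d <- ade_d <- tau_d <- numeric(n_sim)
  chunk <- max(1L, min(n_sim, floor(4e6 / n)))
  with_seed(seed, {
    done <- 0L
    while (done < n_sim) {
      B <- min(chunk, n_sim - done)
      Bm <- MASS::mvrnorm(B, coef_m, vcov_m)
      Bo <- MASS::mvrnorm(B, coef_o, vcov_o)
      if (B == 1L) { Bm <- matrix(Bm, 1); Bo <- matrix(Bo, 1) }
      E <- matrix(stats::rnorm(n * B, 0, sigma), n, B)
      Mt <- Xm_t %*% t(Bm) + E            # n x B counterfactual mediators
      Mc <- Xm_c %*% t(Bm) + E
      eta0 <- Xo0 %*% t(Bo)
      be <- Bo[, exp_o]; bw <- Bo[, med_o]
      bwrep <- rep(bw, each = n)
      eta_t <- sweep(eta0, 2, treat * be, "+")
      eta_c <- sweep(eta0, 2, control * be, "+")
      p_tt <- colMeans(linkinv(eta_t + Mt * bwrep))
      p_tc <- colMeans(linkinv(eta_t + Mc * bwrep))
      p_ct <- colMeans(linkinv(eta_c + Mt * bwrep))
      p_cc <- colMeans(linkinv(eta_c + Mc * bwrep))
      idx <- done + seq_len(B)
      acme_d[idx] <- ((p_tt - p_tc) + (p_ct - p_cc)) / 2
      ade_d[idx] <- ((p_tt - p_ct) + (p_tc - p_cc)) / 2
      tau_d[idx] <- p_tt - p_cc
      done <- done + B
    }
  })

  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  acme <- mean(acme_d); ade <- mean(ade_d); total <- mean(tau_d)
  prop <- if (total != 0 && sign(acme) == sign(total)) acme / total else NA_real_
  structure(list(acme = acme, ade = ade, total = total,
                 prop_mediated = prop,
                 acme_ci = ci(acme_d), ade_ci = ci(ade_d),
                 total_ci = ci(tau_d),
                 n_sim = n_sim, seed = seed, treat = treat, control = control,
                 draws = if (keep_draws)
                   list(acme = acme_d, ade = ade_d, total = tau_d)),
            class = "mediation_result")
}

#' Mediation of an exposure-outcome association by a composite score
#'
#' Convenience wrapper: builds the composite score over `subset`, fits the
#' linear mediator model and the logistic outcome model with a shared
#' covariate structure, and runs [acme_quasi_bayes()] with a per-SD exposure
#' contrast (control = mean BMI, treat = mean + 1 SD on the standardized
#' scale).
#'
#' @param Z standardized metabolite matrix.
#' @param bmi continuous exposure (z-scored internally).
#' @param outcome binary 0/1 outcome.
#' @param covariates optional covariate data.frame.
#' @param model an `spls_model` supplying the weights.
#' @param subset metabolite ids forming the composite score.
#' @inheritParams acme_quasi_bayes
#' @return a `mediation_result`.
#' @export
mediate_composite <- function(Z, bmi, outcome, covariates = NULL, model,
                              subset = selected_metabolites(model),
                              n_sim = 10000L, seed = NULL,
                              keep_draws = FALSE) {
  y <- check_binary(outcome)
  s <- as.numeric(composite_score(Z, model, subset))
  b <- as.numeric(standardize_predictor(bmi))
  df <- data.frame(.y = y, score = s, bmi = b)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cov_terms <- setdiff(names(df), c(".y", "score", "bmi"))
  rhs <- paste(c("bmi", cov_terms), collapse = " + ")
  med_fit <- stats::lm(stats::as.formula(paste("score ~", rhs)), data = df)
  out_fit <- stats::glm(stats::as.formula(paste(".y ~ bmi + score",
                                                if (length(cov_terms))
                                                  paste("+", paste(cov_terms, collapse = " + "))
                                                else "")),
                        data = df, family = stats::binomial())
  acme_quasi_bayes(med_fit, out_fit, exposure = "bmi",
                   treat = 1, control = 0, n_sim = n_sim, seed = seed,
                   keep_draws = keep_draws)
}

#' Backward elimination of metabolites by mediation gain
#'
#' Starting from the sPLS-selected metabolites, repeatedly recomputes the
#' composite score without each candidate metabolite, re-estimates the ACME,
#' and drops the metabolite whose removal yields the largest ACME provided
#' it exceeds the current set's ACME; stops when no single removal increases
#' the ACME or the set reaches `min_size`.  All ACME evaluations share one
#' derived seed (common random numbers), so candidate comparisons are free
#' of Monte-Carlo ranking noise and the accepted ACME sequence is strictly
#' increasing.
#'
#' @inheritParams mediate_composite
#' @param n_sim parameter draws per ACME evaluation (10,000 for final
#'   inference; smaller for exploration).
#' @param seed integer seed for the whole elimination run.
#' @param min_size minimum retained subset size (default 2).
#' @return an `elimination_trace`: `initial_set`, `initial` (the starting
#'   `mediation_result`), `steps` (data.frame: step, removed_id, acme,
#'   ci_low, ci_high), `final_set`, `final` (the retained subset's
#'   `mediation_result`), `stopping_reason` (`"no_gain"` or `"min_size"`),
#'   `n_sim`, `seed`.
#' @export
backward_eliminate <- function(Z, bmi, outcome, covariates = NULL, model,
                               n_sim = 10000L, seed = NULL, min_size = 2L) {
  min_size <- check_count(min_size, "min_size", min = 1L)
  current <- selected_metabolites(model)
  if (length(current) < min_size)
    stop(sprintf("model has %d selected metabolites, fewer than min_size = %d",
                 length(current), min_size), call. = FALSE)
  seed_eval <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  eval_acme <- function(subset) {
    tryCatch(
      mediate_composite(Z, bmi, outcome, covariates, model, subset,
                        n_sim = n_sim, seed = seed_eval),
      error = function(e)
        stop(sprintf("mediation fit failed for subset without [%s]: %s",
                     paste(setdiff(current, subset), collapse = ", "),
                     conditionMessage(e)), call. = FALSE))
  }

  cur_res <- eval_acme(current)
  initial <- cur_res
  steps <- list()
  reason <- "no_gain"
  if (length(current) == min_size) {
    reason <- "min_size"
  } else {
    repeat {
      cand_res <- lapply(current, function(j) eval_acme(setdiff(current, j)))
      acmes <- vapply(cand_res, `[[`, numeric(1), "acme")
      best <- which.max(acmes)
      if (acmes[best] <= cur_res$acme) { reason <- "no_gain"; break }
      removed <- current[best]
      cur_res <- cand_res[[best]]
      current <- setdiff(current, removed)
      steps[[length(steps) + 1L]] <-
        data.frame(step = length(steps) + 1L, removed_id = removed,
                   acme = cur_res$acme, ci_low = cur_res$acme_ci[1],
                   ci_high = cur_res$acme_ci[2], stringsAsFactors = FALSE)
      if (length(current) == min_size) { reason <- "min_size"; break }
    }
  }
  structure(list(initial_set = selected_metabolites(model),
                 initial = initial,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(step = integer(), removed_id = character(),
                                         acme = numeric(), ci_low = numeric(),
                                         ci_high = numeric()),
                 final_set = current, final = cur_res,
                 stopping_reason = reason, n_sim = n_sim, seed = seed),
            class = "elimination_trace")
}

#' Compare the full score against the mediating-subset score
#'
#' Fits the outcome on the full metabolite score (plus BMI and covariates),
#' then adds the subset score, and tests the addition with a 1-df
#' likelihood ratio test.
#'
#' @param outcome binary 0/1 vector.
#' @param full_score,subset_score z-scored composite scores on the same
#'   samples.
#' @param bmi continuous BMI.
#' @param covariates optional covariates.
#' @return list with `fit_full_score` (reduced model), `fit_with_subset`
#'   (full model) and `lrt`.
#' @export
compare_full_vs_subset <- function(outcome, full_score, subset_score, bmi,
                                   covariates = NULL) {
  y <- check_binary(outcome)
  df <- data.frame(.y = y,
                   full_score = as.numeric(standardize_predictor(full_score)),
                   bmi = as.numeric(standardize_predictor(bmi)))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  reduced <- glm_logistic(df, "outcome", focal = "full_score",
                          formula_desc = "outcome ~ full_score + bmi + covariates")
  df$subset_score <- as.numeric(standardize_predictor(subset_score))
  full <- glm_logistic(df, "outcome", focal = "subset_score",
                       formula_desc = "outcome ~ full_score + subset_score + bmi + covariates")
  list(fit_full_score = reduced, fit_with_subset = full,
       lrt = likelihood_ratio_test(full, reduced))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Causal mediation (quasi-Bayesian, %d draws)\n", x$n_sim))
  cat(sprintf("  ACME  %+.4f [%+.4f, %+.4f]\n", x$acme, x$acme_ci[1], x$acme_ci[2]))
  cat(sprintf("  ADE   %+.4f [%+.4f, %+.4f]\n", x$ade, x$ade_ci[1], x$ade_ci[2]))
  cat(sprintf("  Total %+.4f [%+.4f, %+.4f]\n", x$total, x$total_ci[1], x$total_ci[2]))
  if (!is.na(x$prop_mediated))
    cat(sprintf("  Proportion mediated %.2f\n", x$prop_mediated))
  invisible(x)
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("Backward elimination: %d -> %d metabolites (%s)\n",
              length(x$initial_set), length(x$final_set), x$stopping_reason))
  cat(sprintf("  initial ACME %+.4f, final ACME %+.4f over %d removals\n",
              x$initial$acme, x$final$acme, nrow(x$steps)))
  invisible(x)
}
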
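## Multivariable logistic association models
##
## Binary pregnancy complications are related to BMI and to the metabolite
## score through glm(binomial) fits; continuous exposures are z-scored so
## odds ratios read per SD of the predictor.  Inference is Wald (normal-tail
## p, exp(estimate +/- 1.959964 * SE) intervals); nested models are compared
## by the likelihood ratio test on the chi-squared distribution.

WALD_Z <- 1.959964

#' Z-score a continuous predictor
#'
#' @param v numeric vector with positive SD.
#' @return the z-scored vector with attributes `center` and `scale`.
#' @export
standardize_predictor <- function(v) {
  if (anyNA(v)) stop("predictor contains NA; impute or drop first", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("predictor has zero SD; cannot standardize", call. = FALSE)
  structure((v - mean(v)) / s, center = mean(v), scale = s)
}

## shared glm wrapper building a logistic_fit
glm_logistic <- function(df, outcome_name, focal, formula_desc) {
  terms <- setdiff(names(df), ".y")
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = df, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; aliased term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  if (!fit$converged || max(abs(cf)) > 15)
    stop("logistic fit did not converge (possible complete separation)",
         call. = FALSE)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    z = sm[, 3], p = 2 * stats::pnorm(-abs(sm[, 3])),
                    or = exp(sm[, 1]),
                    ci_low = exp(sm[, 1] - WALD_Z * sm[, 2]),
                    ci_high = exp(sm[, 1] + WALD_Z * sm[, 2]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, log_lik = as.numeric(stats::logLik(fit)),
                 n = stats::nobs(fit), n_params = length(cf),
                 outcome = outcome_name, focal = focal,
                 formula = formula_desc, glm = fit),
            class = "logistic_fit")
}

check_binary <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 without NA", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; model inestimable", call. = FALSE)
  as.numeric(y)
}

#' Logistic regression of a binary outcome on a continuous exposure
#'
#' Maximum-likelihood fit (IRLS) of
#' `outcome ~ exposure + covariates`, reporting the exposure's per-SD odds
#' ratio with Wald 95% CI and two-sided p-value.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure continuous exposure; z-scored internally unless
#'   `standardize_exposure = FALSE`.
#' @param covariates optional data.frame of adjustment covariates.
#' @param exposure_name,outcome_name labels used in the coefficient table.
#' @param standardize_exposure z-score the exposure (per-SD odds ratios).
#' @return a `logistic_fit`: coefficient table (term, estimate, se, z, p,
#'   or, ci_low, ci_high), log-likelihood, n, focal term.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         exposure_name = "exposure", outcome_name = "outcome",
                         standardize_exposure = TRUE) {
  y <- check_binary(outcome)
  if (standardize_exposure) exposure <- as.numeric(standardize_predictor(exposure))
  df <- data.frame(.y = y, e = exposure)
  names(df)[2] <- exposure_name
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  glm_logistic(df, outcome_name, focal = exposure_name,
               formula_desc = paste(outcome_name, "~", exposure_name,
                                    if (!is.null(covariates))
                                      paste("+", paste(names(covariates), collapse = " + "))
                                    else ""))
}

#' BMI-adjusted metabolite-score model
#'
#' Fits `outcome ~ score + bmi + covariates` and reports the score's
#' conditional per-SD odds ratio, testing whether the metabolite score
#' carries information beyond measured BMI.
#'
#' @param outcome binary 0/1 vector.
#' @param score metabolite score (z-scored internally).
#' @param bmi continuous BMI (z-scored internally).
#' @param covariates optional adjustment covariates.
#' @param outcome_name label.
#' @return a `logistic_fit` with focal term `"score"`.
#' @export
adjusted_score_model <- function(outcome, score, bmi, covariates = NULL,
                                 outcome_name = "outcome") {
  y <- check_binary(outcome)
  df <- data.frame(.y = y,
                   score = as.numeric(standardize_predictor(score)),
                   bmi = as.numeric(standardize_predictor(bmi)))
  if (!is.null(covariates)) df <- cbind(df, covariates)
  glm_logistic(df, outcome_name, focal = "score",
               formula_desc = paste(outcome_name, "~ score + bmi",
                                    if (!is.null(covariates)) "+ covariates" else ""))
}

#' Likelihood ratio test of nested logistic models
#'
#' @param full,reduced `logistic_fit` objects on the same samples, with the
#'   reduced model's terms a subset of the full model's.
#' @return an `lrt_result`: `statistic = 2 * (llf - llr)`, `df` (parameter
#'   difference), `p` (upper chi-squared tail; identical models give
#'   statistic 0, p = 1).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"))
  if (full$n != reduced$n)
    stop("models were fitted on different numbers of samples; LRT invalid",
         call. = FALSE)
  if (!all(reduced$coefficients$term %in% full$coefficients$term))
    stop("models are not nested: reduced model has terms absent from the full model",
         call. = FALSE)
  stat <- 2 * (full$log_lik - reduced$log_lik)
  if (stat < -1e-8)
    stop("full model has lower likelihood than the reduced model; models are not nested",
         call. = FALSE)
  stat <- max(stat, 0)
  df <- full$n_params - reduced$n_params
  p <- if (df == 0L) {
    if (stat < 1e-8) 1 else NA_real_
  } else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p), class = "lrt_result")
}

#' Association table across outcomes and exposures
#'
#' One covariate-adjusted logistic model per (outcome, exposure) pair, with
#' per-SD odds ratios.  No multiple-comparison adjustment is applied to this
#' table.
#'
#' @param outcomes data.frame of binary 0/1 outcome columns.
#' @param exposures named list (or data.frame) of continuous exposure
#'   vectors.
#' @param covariates optional adjustment covariates.
#' @return data.frame with one row per pair: outcome, exposure, n, estimate,
#'   se, or, ci_low, ci_high, p, and a formatted `pretty` column.
#' @export
association_table <- function(outcomes, exposures, covariates = NULL) {
  stopifnot(is.data.frame(outcomes))
  exposures <- as.list(exposures)
  rows <- list()
  for (on in names(outcomes)) {
    for (en in names(exposures)) {
      fit <- fit_logistic(outcomes[[on]], exposures[[en]], covariates,
                          exposure_name = en, outcome_name = on)
      cf <- fit$coefficients[fit$coefficients$term == en, ]
      rows[[length(rows) + 1L]] <-
        data.frame(outcome = on, exposure = en, n = fit$n,
                   estimate = cf$estimate, se = cf$se, or = cf$or,
                   ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
                   pretty = format_or(cf$or, cf$ci_low, cf$ci_high),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Format / parse an odds ratio with its confidence interval
#'
#' `format_or(1.9, 1.29, 2.74)` gives `"1.90 [1.29-2.74]"`;
#' `parse_or()` inverts it.
#'
#' @param or,ci_low,ci_high numeric scalars (vectorised).
#' @param digits decimal places.
#' @return `format_or`: character; `parse_or`: data.frame
#'   `(or, ci_low, ci_high)`.
#' @export
format_or <- function(or, ci_low, ci_high, digits = 2) {
  sprintf(paste0("%.", digits, "f [%.", digits, "f-%.", digits, "f]"),
          or, ci_low, ci_high)
}

#' @rdname format_or
#' @param x character vector produced by `format_or`.
#' @export
parse_or <- function(x) {
  m <- regmatches(x, regexec("^([0-9.]+) \\[([0-9.]+)-([0-9.]+)\\]$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop(sprintf("unparseable odds-ratio string: %s", x[bad][1]), call. = FALSE)
  data.frame(or = as.numeric(vapply(m, `[`, character(1), 2)),
             ci_low = as.numeric(vapply(m, `[`, character(1), 3)),
             ci_high = as.numeric(vapply(m, `[`, character(1), 4)))
}

#' First principal component of a set of socio-demographic variables
#'
#' Helper for building a single "social circumstances" covariate from
#' variables such as household income, maternal education and maternal age:
#' categorical columns are one-hot expanded, all columns centred/scaled,
#' and the first principal component score is returned, z-scored and
#' oriented to correlate positively with the first input column.
#'
#' @param df data.frame of numeric and categorical columns (complete).
#' @return numeric PC1 score vector.
#' @export
first_pc_score <- function(df) {
  stopifnot(is.data.frame(df), !anyNA(df))
  X <- stats::model.matrix(~ . - 1, data = df)
  X <- scale(X)
  X <- X[, apply(X, 2, function(c) all(is.finite(c))), drop = FALSE]
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)$x[, 1]
  pc <- zscore(pc, "pc1")
  anchor <- X[, 1]
  if (stats::cor(pc, anchor) < 0) pc <- -pc
  pc
}

#' @export
print.logistic_fit <- function(x, ...) {
  cf <- x$coefficients[x$coefficients$term == x$focal, ]
  cat(sprintf("Logistic model %s (n = %d)\n", x$formula, x$n))
  cat(sprintf("  %s: OR %s, p = %.3g\n", x$focal,
              format_or(cf$or, cf$ci_low, cf$ci_high), cf$p))
  invisible(x)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}
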
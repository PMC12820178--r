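## Synthetic cohort generator
##
## Emulates a pregnancy-cohort metabolomics study: a latent maternal adiposity
## factor drives both pre-pregnancy BMI and a sparse subset of blood
## metabolites; a further subset of those signal metabolites carries effects
## on binary pregnancy complications, so their contribution to the BMI ->
## outcome association is a mediated path by construction.  Every generated
## cohort ships with a truth record so downstream stages can be validated
## against planted ground truth.

#' Specify one binary pregnancy-complication outcome
#'
#' @param name outcome column name (e.g. `"gestational_diabetes"`).
#' @param prevalence baseline prevalence in (0,1), i.e. the probability at
#'   mean BMI, mean metabolites and reference covariates.
#' @param bmi_logor direct log-odds-ratio per SD of BMI, not routed through
#'   metabolites.
#' @param mediator_logor log-odds-ratio per SD of each mediator metabolite,
#'   expressed relative to the adiposity direction (the realised coefficient
#'   carries the sign of the metabolite's loading, so all mediators route
#'   BMI risk coherently); a single value recycled across mediators, or one
#'   value per mediator.
#' @return a list of class `outcome_spec`.
#' @export
outcome_spec <- function(name, prevalence, bmi_logor = 0, mediator_logor = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  check_fraction(prevalence, paste0("outcome_specs[", name, "]$prevalence"),
                 open = TRUE)
  structure(list(name = name, prevalence = prevalence,
                 bmi_logor = bmi_logor, mediator_logor = mediator_logor),
            class = "outcome_spec")
}

default_outcome_specs <- function() {
  list(
    outcome_spec("gestational_diabetes", 0.045, bmi_logor = 0.20,
                 mediator_logor = 0.30),
    outcome_spec("preeclampsia",        0.040, bmi_logor = 0.15),
    outcome_spec("cesarean_section",    0.210, bmi_logor = 0.20)
  )
}

default_covariate_specs <- function() {
  list(
    bmi_effects     = c(social_circumstances = -0.15, smoking = 0.25,
                        diet_pc1 = 0.10),
    outcome_effects = c(social_circumstances = -0.10, smoking = 0.20)
  )
}

#' Configuration of a synthetic pregnancy cohort
#'
#' Defines the study conditions for [generate_cohort()]: dimensions, the
#' sparse latent BMI signal, the mediator subset, outcome models, covariate
#' confounding, missingness, pathway layout and twin injection.
#'
#' @param n_samples number of pregnancy records (rows).
#' @param n_metabolites number of measured metabolites (columns).
#' @param n_signal number of metabolites loaded on the latent adiposity
#'   factor.
#' @param n_mediators number of signal metabolites that additionally carry
#'   outcome effects (`n_mediators <= n_signal <= n_metabolites`).
#' @param signal_r2 fraction in (0,1) of BMI variance explained by the latent
#'   adiposity factor.
#' @param outcome_specs list of [outcome_spec()] objects.
#' @param covariate_specs list with named numeric vectors `bmi_effects` and
#'   `outcome_effects` giving covariate effects on standardized BMI and on
#'   outcome log-odds.
#' @param missing_rate metabolite-cell missingness rate in \[0, 0.6\].
#' @param missing_mechanism `"MCAR"` or `"outcome_dependent"`; the latter
#'   multiplies each sample's per-cell missingness odds by
#'   `exp(missing_gamma * outcome)`.
#' @param missing_outcome outcome name steering outcome-dependent missingness.
#' @param missing_gamma log-odds shift of missingness per unit of
#'   `missing_outcome`.
#' @param twin_rate fraction of samples belonging to a twin pair (duplicated
#'   `family_id`, shared maternal record, jittered BMI).
#' @param pathway_layout list with `n_sub_pathways` and `concentration`: the
#'   probability that a signal metabolite is assigned to one of a few
#'   designated signal-enriched sub-pathways rather than uniformly.
#' @param bmi_mean,bmi_sd location and scale (kg/m^2) used to place
#'   standardized BMI on its natural scale.
#' @param weight_range range of |loading| of signal metabolites on the latent
#'   factor (log-abundance units per SD of adiposity).
#' @param seed integer seed; fixed seed gives byte-identical cohorts.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 700L,
                          n_metabolites = 640L,
                          n_signal = 46L,
                          n_mediators = 16L,
                          signal_r2 = 0.4,
                          outcome_specs = default_outcome_specs(),
                          covariate_specs = default_covariate_specs(),
                          missing_rate = 0.05,
                          missing_mechanism = c("MCAR", "outcome_dependent"),
                          missing_outcome = NULL,
                          missing_gamma = -0.5,
                          twin_rate = 0.02,
                          pathway_layout = list(n_sub_pathways = 25L,
                                                concentration = 0.6),
                          bmi_mean = 24.5,
                          bmi_sd = 4.3,
                          weight_range = c(0.4, 1.0),
                          seed = 1L) {
  n_samples     <- check_count(n_samples, "n_samples", min = 2L)
  n_metabolites <- check_count(n_metabolites, "n_metabolites", min = 1L)
  n_signal      <- check_count(n_signal, "n_signal", min = 0L)
  n_mediators   <- check_count(n_mediators, "n_mediators", min = 0L)
  if (n_signal > n_metabolites)
    stop_field("n_signal", "must satisfy n_signal <= n_metabolites")
  if (n_mediators > n_signal)
    stop_field("n_mediators", "must satisfy n_mediators <= n_signal")
  check_fraction(signal_r2, "signal_r2", open = TRUE)
  if (!is.list(outcome_specs) || length(outcome_specs) == 0L ||
      !all(vapply(outcome_specs, inherits, logical(1), "outcome_spec")))
    stop_field("outcome_specs", "must be a non-empty list of outcome_spec objects")
  nm <- vapply(outcome_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_field("outcome_specs", "duplicated outcome names")
  check_fraction(missing_rate, "missing_rate", 0, 0.6)
  missing_mechanism <- match.arg(missing_mechanism)
  if (missing_mechanism == "outcome_dependent") {
    if (is.null(missing_outcome) || !missing_outcome %in% nm)
      stop_field("missing_outcome",
                 "must name one of the configured outcomes for the outcome-dependent mechanism")
  }
  check_fraction(twin_rate, "twin_rate", 0, 0.5)
  check_count(pathway_layout$n_sub_pathways, "pathway_layout$n_sub_pathways",
              min = 1L)
  check_fraction(pathway_layout$concentration, "pathway_layout$concentration")
  seed <- check_count(seed, "seed")
  structure(list(n_samples = n_samples, n_metabolites = n_metabolites,
                 n_signal = n_signal, n_mediators = n_mediators,
                 signal_r2 = signal_r2, outcome_specs = outcome_specs,
                 covariate_specs = covariate_specs,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 missing_outcome = missing_outcome,
                 missing_gamma = missing_gamma,
                 twin_rate = twin_rate, pathway_layout = pathway_layout,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 weight_range = weight_range, seed = seed),
            class = "cohort_config")
}

## Pathway assignment: a few designated sub-pathways soak up a fraction
## `concentration` of the signal metabolites so enrichment is recoverable.
assign_pathways <- function(met_ids, signal_ids, layout) {
  n_sub <- layout$n_sub_pathways
  sub_names <- sprintf("SP%02d", seq_len(n_sub))
  supers <- c("Lipid", "Amino Acid", "Carbohydrate", "Xenobiotics",
              "Cofactors and Vitamins")
  super_of <- rep(supers, length.out = n_sub)
  names(super_of) <- sub_names
  assign <- sample(sub_names, length(met_ids), replace = TRUE)
  names(assign) <- met_ids
  n_enriched <- max(1L, min(n_sub, ceiling(n_sub / 8)))
  enriched <- sub_names[seq_len(n_enriched)]
  if (length(signal_ids)) {
    hot <- runif(length(signal_ids)) < layout$concentration
    assign[signal_ids[hot]] <- sample(enriched, sum(hot), replace = TRUE)
  }
  list(assignment = assign,
       annotation = data.frame(metabolite_id = met_ids,
                               sub_pathway = unname(assign[met_ids]),
                               super_pathway = unname(super_of[assign[met_ids]]),
                               stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a latent adiposity factor per pregnancy, builds BMI from it together
#' with confounding covariates and noise (scaled so the latent part explains
#' `signal_r2` of the BMI variance), loads the signal metabolites on the
#' factor with unit log-scale noise, and simulates binary outcomes from a
#' logistic model combining a direct BMI term, per-SD mediator-metabolite
#' terms and covariate terms.  Twin pairs share one maternal record under a
#' duplicated `family_id` with jittered BMI.
#'
#' @param config a [cohort_config()].
#' @param truth optionally, the `truth_record` of a previously generated
#'   cohort; new samples are then drawn from the same planted weights,
#'   mediators, outcome coefficients and pathway layout (an independent
#'   validation cohort from the same truth).
#' @param seed overrides `config$seed` when given.
#' @return a list with components `data` (class `cohort_data`: `abundances`
#'   samples x metabolites positive reals with `NA` at missing cells, `mask`
#'   logical missingness matrix (`TRUE` = missing), `covariates`, `bmi`,
#'   `outcomes`, `family_id`) and `truth` (class `truth_record`:
#'   `signal_ids`, `mediator_ids`, `true_weights`, `true_outcome_coefs`,
#'   `pathway_assignment`, `annotation`).
#' @export
generate_cohort <- function(config, truth = NULL, seed = NULL) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config object", call. = FALSE)
  with_seed(if (is.null(seed)) config$seed else seed, {
    n <- config$n_samples
    p <- config$n_metabolites
    met_ids <- sprintf("M%04d", seq_len(p))
    sample_ids <- sprintf("S%04d", seq_len(n))

    if (is.null(truth)) {
      signal_idx <- sort(sample.int(p, config$n_signal))
      signal_ids <- met_ids[signal_idx]
      mediator_ids <- sort(sample(signal_ids, config$n_mediators))
      w <- numeric(p)
      names(w) <- met_ids
      mag <- runif(config$n_signal, config$weight_range[1], config$weight_range[2])
      sgn <- ifelse(runif(config$n_signal) < 0.7, 1, -1)
      w[signal_ids] <- mag * sgn
      pw <- assign_pathways(met_ids, signal_ids, config$pathway_layout)
      outcome_coefs <- lapply(config$outcome_specs, function(os) {
        ## outcome effect direction follows the metabolite's adiposity
        ## loading, so every mediator routes BMI risk in the same direction
        ## (protective metabolites are negative on both paths)
        ml <- rep_len(os$mediator_logor, length(mediator_ids)) *
          sign(w[mediator_ids])
        names(ml) <- mediator_ids
        list(name = os$name, intercept = stats::qlogis(os$prevalence),
             bmi_logor = os$bmi_logor, mediator_logors = ml,
             covariate_logors = config$covariate_specs$outcome_effects)
      })
      names(outcome_coefs) <- vapply(config$outcome_specs, `[[`,
                                     character(1), "name")
    } else {
      if (!inherits(truth, "truth_record"))
        stop("`truth` must be a truth_record object", call. = FALSE)
      if (length(truth$true_weights) != p)
        stop_field("n_metabolites", "does not match the supplied truth record")
      met_ids <- names(truth$true_weights)
      signal_ids <- truth$signal_ids
      mediator_ids <- truth$mediator_ids
      w <- truth$true_weights
      pw <- list(assignment = truth$pathway_assignment,
                 annotation = truth$annotation)
      outcome_coefs <- truth$true_outcome_coefs
    }

    ## latent adiposity and covariates
    A <- rnorm(n)
    social <- rnorm(n)
    smoking <- as.integer(runif(n) < stats::plogis(stats::qlogis(0.08) - 0.5 * social))
    child_sex <- factor(ifelse(runif(n) < 0.5, "female", "male"),
                        levels = c("female", "male"))
    diet <- matrix(rnorm(3L * n), n, 3L,
                   dimnames = list(NULL, paste0("diet_pc", 1:3)))
    covariates <- data.frame(social_circumstances = social, smoking = smoking,
                             child_sex = child_sex, diet, check.names = FALSE)

    be <- config$covariate_specs$bmi_effects
    cov_part <- numeric(n)
    for (v in names(be)) {
      col <- covariates[[v]]
      if (is.null(col)) stop_field("covariate_specs$bmi_effects",
                                   paste("unknown covariate", v))
      cov_part <- cov_part + be[[v]] * as.numeric(col)
    }
    cov_part <- cov_part - mean(cov_part)
    sig_e <- sqrt(max(1 - config$signal_r2 - stats::var(cov_part), 0.04))
    bmi_z <- sqrt(config$signal_r2) * A + cov_part + rnorm(n, 0, sig_e)
    bmi <- config$bmi_mean + config$bmi_sd * bmi_z

    ## log-abundances: signal metabolites load on A; all get unit noise
    L <- matrix(rnorm(n * p), n, p, dimnames = list(sample_ids, met_ids))
    if (length(signal_ids))
      L[, signal_ids] <- L[, signal_ids] +
        outer(A, w[signal_ids])
    base_mu <- runif(p, 3, 8)

    ## outcomes from logistic models; mediator metabolites enter per SD
    oe <- config$covariate_specs$outcome_effects
    cov_lp <- numeric(n)
    for (v in names(oe)) cov_lp <- cov_lp + oe[[v]] * as.numeric(covariates[[v]])
    cov_lp <- cov_lp - mean(cov_lp)
    outcomes <- as.data.frame(lapply(outcome_coefs, function(oc) {
      lp <- oc$intercept + oc$bmi_logor * bmi_z + cov_lp
      if (length(oc$mediator_logors)) {
        msd <- sqrt(w[names(oc$mediator_logors)]^2 + 1)
        mz <- sweep(L[, names(oc$mediator_logors), drop = FALSE], 2, msd, "/")
        lp <- lp + drop(mz %*% oc$mediator_logors)
      }
      as.integer(runif(n) < stats::plogis(lp))
    }), optional = TRUE)
    rownames(outcomes) <- sample_ids

    ## twins: duplicated family_id sharing the maternal record
    family_id <- sprintf("F%04d", seq_len(n))
    n_pairs <- round(config$twin_rate * n / 2)
    if (n_pairs > 0) {
      pick <- sample.int(n, 2L * n_pairs)
      first <- pick[seq_len(n_pairs)]
      second <- pick[n_pairs + seq_len(n_pairs)]
      family_id[second] <- family_id[first]
      bmi[second] <- bmi[first] + rnorm(n_pairs, 0, 0.3)
      L[second, ] <- L[first, ]
      covariates[second, setdiff(names(covariates), "child_sex")] <-
        covariates[first, setdiff(names(covariates), "child_sex")]
      outcomes[second, ] <- outcomes[first, ]
    }

    abundances <- exp(sweep(L, 2, base_mu, "+"))
    mask <- matrix(FALSE, n, p, dimnames = dimnames(abundances))

    data <- structure(list(abundances = abundances, mask = mask,
                           covariates = covariates, bmi = bmi,
                           outcomes = outcomes, family_id = family_id),
                      class = "cohort_data")
    truth_out <- structure(list(signal_ids = signal_ids,
                                mediator_ids = mediator_ids,
                                true_weights = w,
                                true_outcome_coefs = outcome_coefs,
                                pathway_assignment = pw$assignment,
                                annotation = pw$annotation),
                           class = "truth_record")
    list(data = data, truth = truth_out)
  })
}

#' Apply the configured missingness mechanism to metabolite cells
#'
#' Under MCAR every cell is missing independently at `missing_rate`; under
#' the outcome-dependent mechanism each sample's per-cell missingness odds
#' are multiplied by `exp(missing_gamma * outcome)` for the configured
#' outcome, so missingness associates with that outcome (emulating
#' non-random missingness observed in real cohorts).
#'
#' @param data a `cohort_data` with an all-observed mask.
#' @param config the [cohort_config()] carrying `missing_rate`,
#'   `missing_mechanism`, `missing_outcome`, `missing_gamma`.
#' @param seed integer seed; defaults to a seed derived from `config$seed`.
#' @return `data` with `NA` at missing abundance cells and an updated mask.
#' @export
apply_missingness <- function(data, config, seed = derive_seed(config$seed, 1L)) {
  stopifnot(inherits(data, "cohort_data"), inherits(config, "cohort_config"))
  if (any(data$mask))
    stop("`data` already has missing cells; apply_missingness expects an all-observed mask",
         call. = FALSE)
  rate <- check_fraction(config$missing_rate, "missing_rate", 0, 0.6)
  if (rate == 0) return(data)
  with_seed(seed, {
    n <- nrow(data$abundances); p <- ncol(data$abundances)
    if (config$missing_mechanism == "MCAR") {
      pr <- rep(rate, n)
    } else {
      y <- data$outcomes[[config$missing_outcome]]
      pr <- stats::plogis(stats::qlogis(rate) + config$missing_gamma * y)
    }
    miss <- matrix(runif(n * p) < pr, n, p)  # pr recycles down columns = per sample
    dimnames(miss) <- dimnames(data$abundances)
    data$mask <- miss
    data$abundances[miss] <- NA_real_
    data
  })
}

#' Punch MCAR holes into a covariate table
#'
#' @param covariates data.frame of covariates (mixed types).
#' @param rate cell-wise missingness rate in \[0, 0.3\].
#' @param seed integer seed.
#' @return the covariate table with `NA` holes; categorical columns keep
#'   their original level sets.
#' @export
inject_covariate_missingness <- function(covariates, rate, seed = NULL) {
  stopifnot(is.data.frame(covariates))
  check_fraction(rate, "rate", 0, 0.3)
  if (rate == 0) return(covariates)
  with_seed(seed, {
    for (j in seq_along(covariates)) {
      hole <- runif(nrow(covariates)) < rate
      covariates[hole, j] <- NA
    }
    covariates
  })
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d samples x %d metabolites (%d signal, %d mediators)\n",
              x$n_samples, x$n_metabolites, x$n_signal, x$n_mediators))
  cat(sprintf("  signal_r2 = %.2f; missingness %s at rate %.2f\n",
              x$signal_r2, x$missing_mechanism, x$missing_rate))
  cat(sprintf("  outcomes: %s\n",
              paste(vapply(x$outcome_specs, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Cohort data: %d samples x %d metabolites (%.1f%% cells missing)\n",
              nrow(x$abundances), ncol(x$abundances), 100 * mean(x$mask)))
  cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  cat(sprintf("  outcomes: %s\n", paste(names(x$outcomes), collapse = ", ")))
  invisible(x)
}
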
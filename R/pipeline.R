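## Pipeline orchestration and tabular IO
##
## One reproducible run sequences simulate -> preprocess -> score ->
## associate -> enrich -> mediate.  All tables are tab-separated UTF-8 with
## an empty cell encoding a missing value (tabs tolerate commas inside
## metabolite names such as "ceramide (d18:2/24:1, d18:1/24:2)").  A single
## global seed fans out to per-stage seeds through derive_seed(), so stages
## are independently reproducible.

PIPELINE_STAGES <- c("simulate", "preprocess", "score", "associate",
                     "enrich", "mediate")

#' Configure a pipeline run
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed fanned out to per-stage seeds.
#' @param stages stages to execute, a subset of
#'   `c("simulate","preprocess","score","associate","enrich","mediate")`;
#'   order is fixed, omitted stages are recorded as skipped.
#' @param cohort a [cohort_config()] for the discovery cohort.
#' @param validation generate an independent validation cohort from the same
#'   planted truth.
#' @param validation_n sample size of the validation cohort.
#' @param max_missing metabolite missingness exclusion threshold.
#' @param rf_num_trees,rf_max_iter random-forest imputation settings.
#' @param grid,folds,repeats sPLS tuning settings.
#' @param mediate_outcome outcome carried into the mediation stage.
#' @param n_sim parameter draws per ACME evaluation.
#' @param min_size minimum mediator-set size for backward elimination.
#' @param input_dir cohort directory read when `"simulate"` is not among the
#'   stages.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = PIPELINE_STAGES,
                       cohort = cohort_config(seed = derive_seed(seed, 0L)),
                       validation = TRUE,
                       validation_n = cohort$n_samples,
                       max_missing = 1 / 3,
                       rf_num_trees = 100L,
                       rf_max_iter = 10L,
                       grid = seq(0, 1, by = 0.1),
                       folds = 5L,
                       repeats = 10L,
                       mediate_outcome = "gestational_diabetes",
                       n_sim = 10000L,
                       min_size = 2L,
                       input_dir = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  seed <- check_count(seed, "seed")
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop_field("stages", paste("unknown stage(s):", paste(bad, collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!inherits(cohort, "cohort_config"))
    stop_field("cohort", "must be a cohort_config")
  if (!"simulate" %in% stages && is.null(input_dir))
    stop_field("input_dir", "required when the simulate stage is disabled")
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 cohort = cohort, validation = isTRUE(validation),
                 validation_n = check_count(validation_n, "validation_n", 2L),
                 max_missing = max_missing,
                 rf_num_trees = rf_num_trees, rf_max_iter = rf_max_iter,
                 grid = grid, folds = folds, repeats = repeats,
                 mediate_outcome = mediate_outcome,
                 n_sim = n_sim, min_size = min_size,
                 input_dir = input_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `cohort` key
#' holds [cohort_config()] arguments.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_config, y$cohort)
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

## ---- TSV IO ------------------------------------------------------------

write_tsv <- function(df, path) {
  ## 17 significant digits round-trip doubles exactly
  for (j in which(vapply(df, is.double, logical(1)))) {
    s <- sprintf("%.17g", df[[j]])
    s[is.na(df[[j]])] <- NA_character_
    df[[j]] <- s
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    fileEncoding = "UTF-8")
}

## parse character columns to numeric, reporting the first offending cell
parse_numeric_cols <- function(df, file, skip = character()) {
  for (j in setdiff(names(df), skip)) {
    v <- df[[j]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' at row %d, column '%s'",
                   file, v[bad[1]], bad[1], j), call. = FALSE)
    df[[j]] <- num
  }
  df
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `abundances.tsv` (samples x metabolites, empty cell = missing),
#' `covariates.tsv` (including `family_id` and `bmi`), `outcomes.tsv`,
#' and, when supplied, `annotation.tsv` and `truth.json`.
#'
#' @param data a `cohort_data`.
#' @param dir target directory (created if absent).
#' @param truth optional `truth_record`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(data, dir, truth = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ab <- data.frame(sample_id = rownames(data$abundances),
                   data$abundances, check.names = FALSE)
  write_tsv(ab, file.path(dir, "abundances.tsv"))
  cov <- data.frame(sample_id = rownames(data$abundances),
                    family_id = data$family_id, bmi = data$bmi,
                    data$covariates, check.names = FALSE)
  write_tsv(cov, file.path(dir, "covariates.tsv"))
  out <- data.frame(sample_id = rownames(data$abundances),
                    data$outcomes, check.names = FALSE)
  write_tsv(out, file.path(dir, "outcomes.tsv"))
  if (!is.null(truth)) {
    write_tsv(truth$annotation, file.path(dir, "annotation.tsv"))
    jsonlite::write_json(
      list(signal_ids = truth$signal_ids,
           mediator_ids = truth$mediator_ids,
           true_weights = as.list(truth$true_weights[truth$true_weights != 0]),
           true_outcome_coefs = lapply(truth$true_outcome_coefs, function(oc)
             list(name = oc$name, intercept = oc$intercept,
                  bmi_logor = oc$bmi_logor,
                  mediator_logors = as.list(oc$mediator_logors))),
           pathway_assignment = as.list(truth$pathway_assignment)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates that metabolite ids are unique, that sample ids agree across
#' tables, and that every abundance cell is numeric or empty (missing);
#' violations raise errors naming the offending ids or cell coordinates.
#'
#' @param dir cohort directory.
#' @return list with `data` (a `cohort_data`) and `annotation` (or `NULL`).
#' @export
read_cohort <- function(dir) {
  ab_raw <- read_tsv_raw(file.path(dir, "abundances.tsv"))
  met_ids <- names(ab_raw)[names(ab_raw) != "sample_id"]
  dup <- unique(met_ids[duplicated(met_ids)])
  if (length(dup))
    stop(sprintf("abundances.tsv: duplicated metabolite id(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  ab <- parse_numeric_cols(ab_raw, "abundances.tsv", skip = "sample_id")
  abundances <- as.matrix(ab[met_ids])
  rownames(abundances) <- ab$sample_id

  cov_raw <- read_tsv_raw(file.path(dir, "covariates.tsv"))
  if (!all(c("sample_id", "family_id", "bmi") %in% names(cov_raw)))
    stop("covariates.tsv must contain sample_id, family_id and bmi columns",
         call. = FALSE)
  if (!identical(cov_raw$sample_id, ab$sample_id))
    stop("sample ids differ between abundances.tsv and covariates.tsv",
         call. = FALSE)
  ## numeric except known categorical columns
  cat_cols <- c("sample_id", "family_id", "child_sex")
  cov <- parse_numeric_cols(cov_raw, "covariates.tsv", skip = cat_cols)
  if ("child_sex" %in% names(cov)) {
    cs <- cov$child_sex; cs[cs == ""] <- NA_character_
    cov$child_sex <- factor(cs)
  }
  covariates <- cov[setdiff(names(cov), c("sample_id", "family_id", "bmi"))]

  out_raw <- read_tsv_raw(file.path(dir, "outcomes.tsv"))
  if (!identical(out_raw$sample_id, ab$sample_id))
    stop("sample ids differ between abundances.tsv and outcomes.tsv",
         call. = FALSE)
  out <- parse_numeric_cols(out_raw, "outcomes.tsv", skip = "sample_id")
  outcomes <- out[setdiff(names(out), "sample_id")]
  rownames(outcomes) <- out$sample_id

  ann_path <- file.path(dir, "annotation.tsv")
  annotation <- if (file.exists(ann_path)) read_tsv_raw(ann_path) else NULL

  data <- structure(list(abundances = abundances,
                         mask = is.na(abundances),
                         covariates = covariates,
                         bmi = cov$bmi,
                         outcomes = outcomes,
                         family_id = cov$family_id),
                    class = "cohort_data")
  list(data = data, annotation = annotation)
}

#' Serialise / load an sPLS model as JSON
#'
#' @param model an `spls_model`.
#' @param path JSON file.
#' @return `save_spls_model`: `path` invisibly; `load_spls_model`: the
#'   `spls_model` (without the tuning trace).
#' @export
save_spls_model <- function(model, path) {
  stopifnot(inherits(model, "spls_model"))
  jsonlite::write_json(
    list(training_column_ids = model$training_column_ids,
         weights = as.list(model$weights),
         eta = model$eta, intercept = model$intercept, slope = model$slope,
         rmsecv = model$rmsecv, r2cv = model$r2cv,
         r2_insample = model$r2_insample,
         training_standardisation = model$training_standardisation,
         response_center_scale = as.list(model$response_center_scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_spls_model
#' @export
load_spls_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(j$weights)
  structure(list(weights = w, eta = j$eta,
                 training_column_ids = j$training_column_ids,
                 intercept = j$intercept, slope = j$slope,
                 r2_insample = j$r2_insample,
                 rmsecv = j$rmsecv, r2cv = j$r2cv, tuning = NULL,
                 training_standardisation = j$training_standardisation,
                 response_center_scale = unlist(j$response_center_scale)),
            class = "spls_model")
}

## ---- orchestration -----------------------------------------------------

## preprocess one cohort: twin de-dup, missingness filter, log-scale RF
## imputation, centre/scale; covariate PCA imputation when holes exist
preprocess_cohort <- function(data, config, seed) {
  data <- dedupe_twins(data, seed = derive_seed(seed, 1L))
  filt <- filter_by_missingness(data$abundances, config$max_missing)
  logm <- filt$matrix
  logm[!is.na(logm)] <- base::log(logm[!is.na(logm)])
  imp <- rf_impute(logm, seed = derive_seed(seed, 2L),
                   max_iter = config$rf_max_iter,
                   num_trees = config$rf_num_trees)
  std <- log_center_scale(imp$matrix, log = FALSE)
  covariates <- data$covariates
  if (anyNA(covariates)) covariates <- pca_impute_covariates(covariates)
  list(data = data, z = std$z, std_params = std$params,
       covariates = covariates, report = filt$report,
       rf_iterations = imp$iterations)
}

#' Execute the pipeline end to end
#'
#' Runs the configured stages in order, persisting each stage's outputs
#' under `config$out_dir` before the next begins, and returns (and writes)
#' a machine-readable run report with per-stage status and summary numbers.
#' A stage failure halts the run with an error naming the stage; outputs of
#' completed stages remain on disk.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a `run_report` (also written to `run_report.json`): `seed`,
#'   `stages` (status + numeric summaries per stage), `timing_s`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  timing <- numeric(0)
  say <- function(...) if (!quiet) message("[metabmi] ", sprintf(...))
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    say("stage %s ...", name)
    t0 <- proc.time()[["elapsed"]]
    summary <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      write_report(report, timing, config$out_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    report$stages[[name]] <<- list(status = "completed", summary = summary)
    invisible()
  }

  run_stage("simulate", function() {
    gen <- generate_cohort(config$cohort,
                           seed = derive_seed(config$seed, 10L))
    disc <- apply_missingness(gen$data, config$cohort,
                              seed = derive_seed(config$seed, 11L))
    env$truth <- gen$truth
    env$discovery <- disc
    dirs <- file.path(config$out_dir, "cohort_discovery")
    write_cohort(disc, dirs, truth = gen$truth)
    out <- list(n_discovery = nrow(disc$abundances),
                n_metabolites = ncol(disc$abundances),
                missing_frac_discovery = round(mean(disc$mask), 4))
    if (config$validation) {
      vcfg <- config$cohort
      vcfg$n_samples <- config$validation_n
      vgen <- generate_cohort(vcfg, truth = gen$truth,
                              seed = derive_seed(config$seed, 12L))
      val <- apply_missingness(vgen$data, vcfg,
                               seed = derive_seed(config$seed, 13L))
      env$validation <- val
      write_cohort(val, file.path(config$out_dir, "cohort_validation"),
                   truth = vgen$truth)
      out$n_validation <- nrow(val$abundances)
    }
    out
  })

  run_stage("preprocess", function() {
    if (is.null(env$discovery)) {
      rd <- read_cohort(file.path(
        if (is.null(config$input_dir)) config$out_dir else config$input_dir,
        "cohort_discovery"))
      env$discovery <- rd$data
      env$annotation <- rd$annotation
    }
    env$prep_disc <- preprocess_cohort(env$discovery, config,
                                       derive_seed(config$seed, 20L))
    rep <- env$prep_disc$report
    jsonlite::write_json(
      list(discovery = list(
        n_input_metabolites = rep$n_input_metabolites,
        n_excluded_missingness = rep$n_excluded_missingness,
        n_samples = nrow(env$prep_disc$z),
        rf_iterations = env$prep_disc$rf_iterations)),
      file.path(config$out_dir, "preprocess_report.json"),
      auto_unbox = TRUE, digits = NA)
    out <- list(n_retained_discovery = ncol(env$prep_disc$z),
                n_excluded_discovery = rep$n_excluded_missingness,
                n_samples_discovery = nrow(env$prep_disc$z))
    if (!is.null(env$validation) ||
        dir.exists(file.path(config$out_dir, "cohort_validation"))) {
      if (is.null(env$validation))
        env$validation <- read_cohort(
          file.path(config$out_dir, "cohort_validation"))$data
      env$prep_val <- preprocess_cohort(env$validation, config,
                                        derive_seed(config$seed, 21L))
      out$n_retained_validation <- ncol(env$prep_val$z)
      out$n_samples_validation <- nrow(env$prep_val$z)
    }
    out
  })

  run_stage("score", function() {
    pd <- env$prep_disc
    y <- as.numeric(standardize_predictor(pd$data$bmi))
    overlap <- if (!is.null(env$prep_val))
      intersect(colnames(pd$z), colnames(env$prep_val$z))
    else colnames(pd$z)
    model <- transfer_fit(pd$z, y, overlap_ids = overlap,
                          grid = config$grid, folds = config$folds,
                          repeats = config$repeats,
                          seed = derive_seed(config$seed, 30L),
                          standardise = FALSE)
    model$training_standardisation <-
      pd$std_params[match(overlap, pd$std_params$id), ]
    model$response_center_scale <- c(mean = mean(pd$data$bmi),
                                     sd = stats::sd(pd$data$bmi))
    env$model <- model
    env$score_disc <- predict_score(model, pd$z[, overlap, drop = FALSE])
    scores <- data.frame(sample_id = rownames(pd$z), cohort = "discovery",
                         score = env$score_disc)
    if (!is.null(env$prep_val)) {
      env$score_val <- predict_score(
        env$model, env$prep_val$z[, overlap, drop = FALSE])
      scores <- rbind(scores,
                      data.frame(sample_id = rownames(env$prep_val$z),
                                 cohort = "validation",
                                 score = env$score_val))
    }
    save_spls_model(model, file.path(config$out_dir, "model.json"))
    write_tsv(scores, file.path(config$out_dir, "scores.tsv"))
    list(selected_eta = model$eta,
         n_selected = length(selected_metabolites(model)),
         n_overlap = length(overlap),
         rmsecv = round(model$rmsecv, 6), r2cv = round(model$r2cv, 6))
  })

  run_stage("associate", function() {
    pd <- env$prep_disc
    tab <- association_table(pd$data$outcomes,
                             list(bmi = pd$data$bmi, score = env$score_disc),
                             covariates = pd$covariates)
    adj <- do.call(rbind, lapply(names(pd$data$outcomes), function(on) {
      fit <- adjusted_score_model(pd$data$outcomes[[on]], env$score_disc,
                                  pd$data$bmi, pd$covariates,
                                  outcome_name = on)
      cf <- fit$coefficients[fit$coefficients$term == "score", ]
      data.frame(outcome = on, exposure = "score_adj_bmi", n = fit$n,
                 estimate = cf$estimate, se = cf$se, or = cf$or,
                 ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
                 pretty = format_or(cf$or, cf$ci_low, cf$ci_high),
                 stringsAsFactors = FALSE)
    }))
    tab <- rbind(tab, adj)
    write_tsv(tab, file.path(config$out_dir, "associations.tsv"))
    env$assoc <- tab
    list(n_models = nrow(tab),
         min_p = signif(min(tab$p), 6))
  })

  run_stage("enrich", function() {
    ann <- if (!is.null(env$truth)) env$truth$annotation else env$annotation
    if (is.null(ann)) stop("no annotation table available", call. = FALSE)
    et <- enrich(selected_metabolites(env$model), ann,
                 background_ids = env$model$training_column_ids)
    write_tsv(et, file.path(config$out_dir, "enrichment.tsv"))
    env$enrichment <- et
    list(n_pathways_tested = nrow(et),
         n_fdr_hits = sum(et$q_fdr < 0.05),
         top_fold = round(et$fold_enrichment[1], 4),
         top_p = signif(et$p[1], 6))
  })

  run_stage("mediate", function() {
    pd <- env$prep_disc
    on <- config$mediate_outcome
    if (!on %in% names(pd$data$outcomes))
      stop(sprintf("mediation outcome '%s' not among outcomes", on),
           call. = FALSE)
    overlap <- env$model$training_column_ids
    trace <- backward_eliminate(pd$z[, overlap, drop = FALSE],
                                pd$data$bmi, pd$data$outcomes[[on]],
                                pd$covariates, env$model,
                                n_sim = config$n_sim,
                                seed = derive_seed(config$seed, 40L),
                                min_size = config$min_size)
    subset_score <- composite_score(pd$z, env$model, trace$final_set)
    cmp <- compare_full_vs_subset(pd$data$outcomes[[on]], env$score_disc,
                                  subset_score, pd$data$bmi, pd$covariates)
    jsonlite::write_json(
      list(outcome = on,
           initial_set = trace$initial_set,
           final_set = trace$final_set,
           stopping_reason = trace$stopping_reason,
           initial_acme = trace$initial$acme,
           final_acme = trace$final$acme,
           final_acme_ci = trace$final$acme_ci,
           prop_mediated = trace$final$prop_mediated,
           steps = trace$steps,
           lrt = list(statistic = cmp$lrt$statistic, df = cmp$lrt$df,
                      p = cmp$lrt$p)),
      file.path(config$out_dir, "mediation_trace.json"),
      auto_unbox = TRUE, digits = NA)
    env$trace <- trace
    list(n_initial = length(trace$initial_set),
         n_final = length(trace$final_set),
         initial_acme = signif(trace$initial$acme, 6),
         final_acme = signif(trace$final$acme, 6),
         lrt_p = signif(cmp$lrt$p, 6))
  })

  report$timing_s <- as.list(timing)
  write_report(report, timing, config$out_dir)
  structure(c(report, list(objects = as.list(env))), class = "run_report")
}

write_report <- function(report, timing, out_dir) {
  jsonlite::write_json(c(report["seed"], report["stages"],
                         list(timing_s = as.list(timing))),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %s", s, st$status))
    if (!is.null(st$summary))
      cat(": ", paste(names(st$summary),
                      vapply(st$summary, function(v) format(v), character(1)),
                      sep = "=", collapse = ", "), sep = "")
    cat("\n")
  }
  invisible(x)
}
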
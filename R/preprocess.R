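## Metabolome preprocessing
##
## Order of operations mirrors common practice for untargeted panels:
## exclude metabolites with excessive missingness, impute the remainder with
## an iterative random-forest scheme, then log/centre/scale.  Imputation is
## performed on the log scale, where the abundances are approximately
## Gaussian and the forest regressions are best behaved.

#' Exclude metabolites with excessive missingness
#'
#' Metabolites whose missing fraction is strictly greater than
#' `max_missing_frac` are removed ("more than" a third missing excludes;
#' exactly a third is retained).  Survivor order is preserved.
#'
#' @param x samples x metabolites numeric matrix with `NA` at missing cells.
#' @param max_missing_frac exclusion threshold (default 1/3).
#' @return list with `matrix` (filtered) and `report`, a `preprocess_report`
#'   carrying input/excluded counts and per-metabolite missing fractions.
#' @export
filter_by_missingness <- function(x, max_missing_frac = 1 / 3) {
  stopifnot(is.matrix(x), is.numeric(x))
  check_fraction(max_missing_frac, "max_missing_frac")
  frac <- colMeans(is.na(x))
  keep <- frac <= max_missing_frac
  if (!any(keep))
    stop("all metabolites exceed the missingness threshold; empty matrix refused",
         call. = FALSE)
  report <- structure(list(n_input_metabolites = ncol(x),
                           n_excluded_missingness = sum(!keep),
                           missing_frac = frac,
                           excluded_ids = colnames(x)[!keep],
                           threshold = max_missing_frac),
                      class = "preprocess_report")
  list(matrix = x[, keep, drop = FALSE], report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("Missingness filter: %d of %d metabolites excluded (> %.1f%% missing)\n",
              x$n_excluded_missingness, x$n_input_metabolites,
              100 * x$threshold))
  invisible(x)
}

## seed for the ranger fit of column j in sweep `iter`; shared derivation so
## a single sweep is exactly reproducible
rf_fit_seed <- function(seed, iter, j) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 7919 * iter + j) %% 2147483629)
}

#' Iterative random-forest imputation of a metabolite matrix
#'
#' missForest-style chained imputation: missing cells are initialised with
#' column means; then, sweeping columns in order of decreasing missingness
#' (ties by column index), each incomplete column is regressed on all other
#' columns with a random forest fitted on its observed rows, and its missing
#' rows are replaced by forest predictions.  Sweeps repeat until the relative
#' change in the imputed values increases (the previous sweep's matrix is
#' then returned) or `max_iter` is reached.  Observed cells are never
#' altered.  The scheme makes no missing-at-random assumption.
#'
#' @param x samples x metabolites numeric matrix with `NA` at missing cells
#'   (typically log-scale abundances).
#' @param seed integer seed controlling forest randomness.
#' @param max_iter maximum number of sweeps.
#' @param num_trees trees per forest.
#' @return list with `matrix` (complete), `iterations` (sweeps actually
#'   used) and `converged` (logical: stopped by the error criterion).
#' @export
rf_impute <- function(x, seed = NULL, max_iter = 10L, num_trees = 100L) {
  stopifnot(is.matrix(x), is.numeric(x))
  miss <- is.na(x)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop(sprintf("column(s) entirely missing: %s",
                 paste(colnames(x)[all_missing], collapse = ", ")),
         call. = FALSE)
  if (!any(miss))
    return(list(matrix = x, iterations = 0L, converged = TRUE))

  imp <- x
  cm <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) imp[miss[, j], j] <- cm[j]

  n_miss <- colSums(miss)
  order_cols <- order(-n_miss, seq_len(ncol(x)))
  order_cols <- order_cols[n_miss[order_cols] > 0L]

  prev <- imp
  prev_err <- Inf
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (j in order_cols) {
      obs <- !miss[, j]
      xj <- imp[, -j, drop = FALSE]
      colnames(xj) <- paste0("V", seq_len(ncol(xj)))  # ranger-safe names
      fit <- ranger::ranger(
        x = xj[obs, , drop = FALSE], y = imp[obs, j],
        num.trees = num_trees, seed = rf_fit_seed(seed, iter, j),
        num.threads = 1L)
      imp[!obs, j] <- stats::predict(fit, data = xj[!obs, , drop = FALSE],
                                     num.threads = 1L)$predictions
    }
    err <- sum((imp[miss] - prev[miss])^2) / max(sum(imp[miss]^2), .Machine$double.eps)
    iterations <- iter
    if (err >= prev_err) {   # error increased: keep the previous sweep
      imp <- prev
      converged <- TRUE
      break
    }
    prev <- imp
    prev_err <- err
  }
  stopifnot(identical(imp[!miss], x[!miss]))
  list(matrix = imp, iterations = iterations, converged = converged)
}

#' Log-transform, centre and scale a complete metabolite matrix
#'
#' Per column: natural log (optional), subtract the mean, divide by the SD.
#' The returned parameters allow reapplying the identical transform to an
#' external cohort ([apply_standardization()]).
#'
#' @param x complete samples x metabolites matrix; strictly positive when
#'   `log = TRUE`.
#' @param log take natural logs first (set `FALSE` if `x` is already on the
#'   log scale).
#' @return list with `z` (standardized matrix) and `params`, a data.frame
#'   `(id, mean, sd)` of per-column log-scale standardisation parameters.
#' @export
log_center_scale <- function(x, log = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x))
    stop("matrix contains missing cells; impute before standardizing", call. = FALSE)
  if (log) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive value at [%s]; log-transform requires strictly positive abundances",
                   paste(bad[1, ], collapse = ", ")), call. = FALSE)
    x <- base::log(x)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(x)[zero], collapse = ", ")), call. = FALSE)
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  list(z = z,
       params = data.frame(id = colnames(x), mean = mu, sd = sdv,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Apply previously learned standardisation parameters
#'
#' @param x matrix whose columns match `params$id` (any order).
#' @param params data.frame `(id, mean, sd)` from [log_center_scale()].
#' @param log take natural logs first.
#' @return standardized matrix with columns ordered as `params$id`.
#' @export
apply_standardization <- function(x, params, log = TRUE) {
  missing_ids <- setdiff(params$id, colnames(x))
  if (length(missing_ids))
    stop(sprintf("matrix lacks column(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  x <- x[, params$id, drop = FALSE]
  if (log) x <- base::log(x)
  sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Keep one pregnancy record per family
#'
#' Twin pairs appear as duplicated `family_id`; one member per family is
#' retained by a seeded uniform draw so observations are independent.
#'
#' @param data a `cohort_data`.
#' @param seed integer seed for the within-family draw.
#' @return the de-duplicated `cohort_data`.
#' @export
dedupe_twins <- function(data, seed = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  if (!anyDuplicated(data$family_id)) return(data)
  keep <- with_seed(seed, {
    idx <- split(seq_along(data$family_id), data$family_id)
    sort(vapply(idx, function(i) if (length(i) == 1L) i else i[sample.int(length(i), 1L)],
                integer(1)))
  })
  data$abundances <- data$abundances[keep, , drop = FALSE]
  data$mask <- data$mask[keep, , drop = FALSE]
  data$covariates <- data$covariates[keep, , drop = FALSE]
  data$bmi <- data$bmi[keep]
  data$outcomes <- data$outcomes[keep, , drop = FALSE]
  data$family_id <- data$family_id[keep]
  data
}

#' Test whether metabolite missingness associates with an outcome
#'
#' Builds a per-sample missingness predictor over a metabolite subset
#' (default: indicator of any missing value in the subset; optionally the
#' missing count) and fits a logistic regression of the outcome on it, with
#' optional covariate adjustment.  A diagnostic for non-random missingness.
#'
#' @param mask logical samples x metabolites matrix, `TRUE` = missing.
#' @param outcome binary 0/1 vector.
#' @param metabolite_subset non-empty character vector of column names.
#' @param covariates optional covariate data.frame.
#' @param predictor `"any"` (indicator) or `"count"`.
#' @return a `logistic_fit` whose focal term is the missingness predictor.
#' @export
missingness_outcome_association <- function(mask, outcome, metabolite_subset,
                                            covariates = NULL,
                                            predictor = c("any", "count")) {
  predictor <- match.arg(predictor)
  if (length(metabolite_subset) == 0L)
    stop("`metabolite_subset` must be non-empty", call. = FALSE)
  missing_ids <- setdiff(metabolite_subset, colnames(mask))
  if (length(missing_ids))
    stop(sprintf("subset metabolite(s) absent from mask: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  sub <- mask[, metabolite_subset, drop = FALSE]
  x <- if (predictor == "any") as.numeric(rowSums(sub) > 0) else rowSums(sub)
  if (stats::sd(x) == 0)
    stop("missingness predictor is constant over the subset; association inestimable",
         call. = FALSE)
  fit_logistic(outcome, x, covariates,
               exposure_name = paste0("missing_", predictor),
               outcome_name = "outcome", standardize_exposure = FALSE)
}

#' Impute missing covariates by one-component iterative PCA
#'
#' Iterative PCA completion: categorical columns are one-hot expanded,
#' missing cells initialised at the observed column means, and the table is
#' repeatedly centred/scaled, reconstructed from its leading `n_components`
#' singular vectors, and its missing cells overwritten by the
#' reconstruction, until the imputed cells change by less than `tol`.
#' Centring and scaling are recomputed from the current completed table at
#' every iteration, so an exactly low-rank table is a fixed point.
#' Categorical cells are re-collapsed to the category with the largest
#' reconstructed indicator.
#'
#' @param covariates data.frame with numeric and factor/character columns,
#'   `NA` at missing cells.
#' @param n_components rank of the reconstruction (default 1).
#' @param tol convergence tolerance on the maximum absolute change of
#'   imputed cells (standardized scale).
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   last iterate is returned.
#' @return completed covariate data.frame with the original column types.
#' @export
pca_impute_covariates <- function(covariates, n_components = 1L, tol = 1e-6,
                                  max_iter = 1000L) {
  stopifnot(is.data.frame(covariates))
  if (!anyNA(covariates)) return(covariates)
  n <- nrow(covariates)
  is_cat <- vapply(covariates, function(c) is.factor(c) || is.character(c),
                   logical(1))
  levs <- lapply(covariates[is_cat], function(c) {
    if (is.factor(c)) levels(c) else sort(unique(c[!is.na(c)]))
  })

  ## one-hot expansion; NA rows of a categorical propagate NA to all its
  ## indicator columns
  blocks <- list(); block_of <- character(0)
  for (v in names(covariates)) {
    col <- covariates[[v]]
    if (is_cat[[v]]) {
      lv <- levs[[v]]
      ind <- matrix(NA_real_, n, length(lv),
                    dimnames = list(NULL, paste0(v, "=", lv)))
      obs <- !is.na(col)
      for (k in seq_along(lv)) ind[obs, k] <- as.numeric(col[obs] == lv[k])
      blocks[[v]] <- ind
      block_of <- c(block_of, rep(v, length(lv)))
    } else {
      blocks[[v]] <- matrix(as.numeric(col), n, 1, dimnames = list(NULL, v))
      block_of <- c(block_of, v)
    }
  }
  X <- do.call(cbind, blocks)
  obs_n <- colSums(!is.na(X))
  if (any(obs_n < 2L))
    stop(sprintf("column(s) with fewer than 2 observed values: %s",
                 paste(colnames(X)[obs_n < 2L], collapse = ", ")), call. = FALSE)

  miss <- is.na(X)
  Xc <- X
  mu0 <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) Xc[miss[, j], j] <- mu0[j]

  ## centring/scaling recomputed from the current completed matrix each
  ## iteration, so a rank-`n_components` table is an exact fixed point
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(Xc)
    sdv <- apply(Xc, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Z <- sweep(sweep(Xc, 2, mu, "-"), 2, sdv, "/")
    sv <- svd(Z, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    rec <- sv$u %*% (d * t(sv$v))
    new_vals <- sweep(sweep(rec, 2, sdv, "*"), 2, mu, "+")[miss]
    delta <- max(abs(new_vals - Xc[miss]))
    Xc[miss] <- new_vals
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("PCA imputation did not converge in %d iterations (last change %.2e); returning last iterate",
                    max_iter, delta))

  Xhat <- Xc
  out <- covariates
  for (v in names(covariates)) {
    cols <- which(block_of == v)
    na_rows <- is.na(covariates[[v]])
    if (!any(na_rows)) next
    if (is_cat[[v]]) {
      sub <- Xhat[, cols, drop = FALSE]
      pick <- levs[[v]][max.col(sub[na_rows, , drop = FALSE], ties.method = "first")]
      if (is.factor(covariates[[v]])) {
        out[[v]][na_rows] <- factor(pick, levels = levs[[v]])
      } else out[[v]][na_rows] <- pick
    } else {
      out[[v]][na_rows] <- Xhat[na_rows, cols]
    }
  }
  attr(out, "pca_impute") <- list(iterations = iter, converged = converged)
  out
}
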
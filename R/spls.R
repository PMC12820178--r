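## Sparse partial least squares BMI score
##
## One-component sPLS in the soft-thresholded-direction family: the PLS
## direction for standardized data is proportional to the vector of
## column-response correlations; sparsity soft-thresholds that vector at a
## fraction `eta` of its largest absolute entry.  At eta = 0 the model is
## exact one-component PLS.  Sparsity is tuned by repeated k-fold
## cross-validated RMSE, with all standardisation re-learned inside each
## training fold to avoid leakage.

#' Fit a one-component sparse PLS model
#'
#' Computes the correlation `c_j` of every standardized metabolite with the
#' standardized response, soft-thresholds
#' `w_j = sign(c_j) * max(0, |c_j| - eta * max|c|)`, normalises `w` to unit
#' length, forms the score `s = Z w`, and regresses the response on the
#' score.  The weight sign is fixed so that the score correlates positively
#' with the response (higher score = higher predicted BMI).
#'
#' @param Z column-standardized samples x metabolites matrix.
#' @param y standardized response (BMI per SD).
#' @param eta sparsity in \[0, 1\]; larger is sparser.  An `eta` that
#'   thresholds every weight to zero is an error.
#' @return an object of class `spls_model`: `weights` (named, sparse),
#'   `eta`, `training_column_ids`, `intercept`/`slope` of the score->response
#'   regression, `r2_insample`, and slots `rmsecv`/`r2cv`/`tuning` filled by
#'   [fit_bmi_score()], plus `training_standardisation` /
#'   `response_center_scale` when fitted through the high-level interface.
#' @export
fit_spls_one_component <- function(Z, y, eta) {
  stopifnot(is.matrix(Z), nrow(Z) == length(y))
  check_fraction(eta, "eta")
  if (is.null(colnames(Z)))
    colnames(Z) <- sprintf("X%d", seq_len(ncol(Z)))
  cc <- suppressWarnings(drop(stats::cor(Z, y)))
  cc[!is.finite(cc)] <- 0       # constant training column carries no signal
  if (all(cc == 0))
    stop("response is uncorrelated with every column; no direction to fit",
         call. = FALSE)
  thr <- eta * max(abs(cc))
  w <- sign(cc) * pmax(abs(cc) - thr, 0)
  if (all(w == 0))
    stop(sprintf("eta = %g thresholds all weights to zero; choose a smaller eta",
                 eta), call. = FALSE)
  w <- w / sqrt(sum(w^2))
  s <- drop(Z %*% w)
  if (stats::cor(s, y) < 0) { w <- -w; s <- -s }
  fit <- stats::lm.fit(cbind(1, s), y)
  names(w) <- colnames(Z)
  structure(list(weights = w, eta = eta,
                 training_column_ids = colnames(Z),
                 intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 r2_insample = stats::cor(s, y)^2,
                 rmsecv = NA_real_, r2cv = NA_real_, tuning = NULL,
                 training_standardisation = NULL,
                 response_center_scale = NULL),
            class = "spls_model")
}

#' Metabolites with nonzero weight in an sPLS model
#' @param model an `spls_model`.
#' @return character vector of selected metabolite ids.
#' @export
selected_metabolites <- function(model) {
  stopifnot(inherits(model, "spls_model"))
  names(model$weights)[model$weights != 0]
}

## stratified fold assignment: balance fold sizes within response tertiles
make_folds <- function(y, folds, stratify = TRUE) {
  n <- length(y)
  assign <- integer(n)
  groups <- if (stratify) {
    br <- stats::quantile(y, c(1 / 3, 2 / 3))
    split(seq_len(n), findInterval(y, br))
  } else list(seq_len(n))
  for (g in groups) {
    assign[g] <- sample(rep_len(seq_len(folds), length(g)))
  }
  assign
}

#' Tune sPLS sparsity by repeated cross-validated RMSE
#'
#' For each of `repeats` random fold partitions and each fold, the
#' metabolite matrix and response are standardized on the training rows
#' only, a model is fitted at every sparsity on the grid, and held-out
#' responses are predicted through the score regression.  `RMSECV(eta)` is
#' the root mean squared held-out error pooled over folds and repeats (in
#' the units of the incoming response, i.e. response-SD units when `y` is
#' standardized), and `R2CV(eta) = 1 - SSE/SST` with SST taken about the
#' training-fold mean.  The selected sparsity minimises RMSECV; ties go to
#' the sparser model.  Grid values at which the fit degenerates in some fold
#' (all weights thresholded away, e.g. eta = 1) are recorded as `NA` and
#' excluded from selection.
#'
#' @param Z samples x metabolites matrix (standardisation happens per fold).
#' @param y response vector.
#' @param grid sparsity grid (default 0 to 1 in steps of 0.1, 11 values).
#' @param folds number of CV segments (default 5).
#' @param repeats number of repeated partitions (default 10).
#' @param seed integer seed for the fold draws.
#' @param stratify stratify folds by response tertile.
#' @return a `tuning_result`: `grid`, per-eta `rmsecv`/`r2cv`, across-repeat
#'   `rmsecv_sd`, `selected_eta`, `folds`, `repeats`, `seed`.
#' @export
tune_sparsity <- function(Z, y, grid = seq(0, 1, by = 0.1), folds = 5L,
                          repeats = 10L, seed = NULL, stratify = TRUE) {
  stopifnot(is.matrix(Z), nrow(Z) == length(y))
  if (length(grid) == 0L) stop_field("grid", "must be non-empty")
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats", min = 1L)
  if (nrow(Z) < 2L * folds)
    stop(sprintf("need at least %d samples for %d folds", 2L * folds, folds),
         call. = FALSE)

  ne <- length(grid)
  sse <- matrix(0, repeats, ne)    # held-out squared error, per repeat x eta
  sst <- matrix(0, repeats, ne)
  nobs <- matrix(0L, repeats, ne)
  failed <- rep(FALSE, ne)

  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- make_folds(y, folds, stratify)
      for (f in seq_len(folds)) {
        te <- fold_id == f
        Ztr <- Z[!te, , drop = FALSE]; Zte <- Z[te, , drop = FALSE]
        ytr <- y[!te]; yte <- y[te]
        mu <- colMeans(Ztr)
        sdv <- apply(Ztr, 2, stats::sd)
        sdv[sdv == 0 | !is.finite(sdv)] <- 1
        Ztr_s <- sweep(sweep(Ztr, 2, mu, "-"), 2, sdv, "/")
        Zte_s <- sweep(sweep(Zte, 2, mu, "-"), 2, sdv, "/")
        my <- mean(ytr); sy <- stats::sd(ytr)
        ytr_s <- (ytr - my) / sy
        for (e in seq_len(ne)) {
          fit <- tryCatch(fit_spls_one_component(Ztr_s, ytr_s, grid[e]),
                          error = function(err) NULL)
          if (is.null(fit)) { failed[e] <- TRUE; next }
          s_te <- drop(Zte_s %*% fit$weights)
          yhat <- my + sy * (fit$intercept + fit$slope * s_te)
          sse[r, e] <- sse[r, e] + sum((yte - yhat)^2)
          sst[r, e] <- sst[r, e] + sum((yte - my)^2)
          nobs[r, e] <- nobs[r, e] + length(yte)
        }
      }
    }
  })

  rmsecv_rep <- sqrt(sse / nobs)
  rmsecv <- sqrt(colSums(sse) / colSums(nobs))
  r2cv <- 1 - colSums(sse) / colSums(sst)
  rmsecv[failed] <- NA_real_
  r2cv[failed] <- NA_real_
  rmsecv_sd <- apply(rmsecv_rep, 2, stats::sd)
  rmsecv_sd[failed] <- NA_real_
  if (all(failed))
    stop("every sparsity value on the grid degenerated; nothing selectable",
         call. = FALSE)
  best <- min(rmsecv, na.rm = TRUE)
  cand <- which(!is.na(rmsecv) & rmsecv <= best + 1e-12)
  selected <- grid[cand[which.max(grid[cand])]]   # ties -> sparsest model
  structure(list(grid = grid, rmsecv = rmsecv, r2cv = r2cv,
                 rmsecv_sd = rmsecv_sd, selected_eta = selected,
                 folds = folds, repeats = repeats, seed = seed,
                 stratify = stratify),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("sPLS sparsity tuning (", x$repeats, "x ", x$folds, "-fold CV)\n", sep = "")
  tab <- data.frame(eta = x$grid, RMSECV = round(x$rmsecv, 4),
                    R2CV = round(x$r2cv, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("selected eta = %g (min RMSECV)\n", x$selected_eta))
  invisible(x)
}

#' Tune and fit the BMI metabolite score on a training cohort
#'
#' Runs [tune_sparsity()] and refits the final model at the selected
#' sparsity on the fully standardized training data, attaching the
#' cross-validated RMSECV and R2CV at the selected sparsity.
#'
#' @inheritParams tune_sparsity
#' @param standardise learn column standardisation from `Z` and response
#'   centre/scale from `y` and store them in the model (set `FALSE` when the
#'   inputs are already standardized and parameters are tracked elsewhere).
#' @return an `spls_model` with `tuning`, `rmsecv`, `r2cv` filled.
#' @export
fit_bmi_score <- function(Z, y, grid = seq(0, 1, by = 0.1), folds = 5L,
                          repeats = 10L, seed = NULL, stratify = TRUE,
                          standardise = TRUE) {
  tuning <- tune_sparsity(Z, y, grid = grid, folds = folds, repeats = repeats,
                          seed = seed, stratify = stratify)
  if (standardise) {
    std <- log_center_scale(Z, log = FALSE)
    Zs <- std$z
    y_cs <- c(mean = mean(y), sd = stats::sd(y))
    ys <- (y - y_cs["mean"]) / y_cs["sd"]
  } else {
    std <- NULL; Zs <- Z; ys <- y; y_cs <- NULL
  }
  model <- fit_spls_one_component(Zs, ys, tuning$selected_eta)
  model$tuning <- tuning
  sel <- which(tuning$grid == tuning$selected_eta)
  model$rmsecv <- tuning$rmsecv[sel]
  model$r2cv <- tuning$r2cv[sel]
  if (standardise) {
    model$training_standardisation <- std$params
    model$response_center_scale <- y_cs
  }
  model
}

#' Project an sPLS score into an external standardized matrix
#'
#' @param model an `spls_model`.
#' @param Z_ext external matrix standardized the same way as the training
#'   matrix; its columns must be exactly the model's training columns (any
#'   order).
#' @param rescale z-score the raw score within the external cohort (the
#'   convention for cross-cohort comparison: scores standardized within
#'   cohort/visit).  With `rescale = FALSE` the raw linear score `Z w` is
#'   returned.
#' @return numeric score vector.
#' @export
predict_score <- function(model, Z_ext, rescale = TRUE) {
  stopifnot(inherits(model, "spls_model"), is.matrix(Z_ext))
  ids <- model$training_column_ids
  missing_ids <- setdiff(ids, colnames(Z_ext))
  extra_ids <- setdiff(colnames(Z_ext), ids)
  if (length(missing_ids) || length(extra_ids))
    stop(sprintf("column mismatch with the model: missing [%s]; extra [%s]",
                 paste(missing_ids, collapse = ", "),
                 paste(extra_ids, collapse = ", ")), call. = FALSE)
  s <- drop(Z_ext[, ids, drop = FALSE] %*% model$weights)
  if (rescale) zscore(s, "score") else s
}

#' Re-tune and refit the score on an overlapping metabolite set
#'
#' For transfer to an external cohort measured on a partially overlapping
#' panel, the training matrix is restricted to the overlap and the whole
#' tuning + fitting procedure is rerun from scratch, yielding a distinct
#' model per external panel.
#'
#' @inheritParams fit_bmi_score
#' @param overlap_ids non-empty subset of `colnames(Z)` shared with the
#'   external panel.
#' @return an `spls_model` indexed by `overlap_ids` only.
#' @export
transfer_fit <- function(Z, y, overlap_ids, grid = seq(0, 1, by = 0.1),
                         folds = 5L, repeats = 10L, seed = NULL,
                         stratify = TRUE, standardise = TRUE) {
  if (length(overlap_ids) == 0L)
    stop_field("overlap_ids", "must be non-empty")
  missing_ids <- setdiff(overlap_ids, colnames(Z))
  if (length(missing_ids))
    stop(sprintf("overlap id(s) not in training matrix: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  fit_bmi_score(Z[, overlap_ids, drop = FALSE], y, grid = grid, folds = folds,
                repeats = repeats, seed = seed, stratify = stratify,
                standardise = standardise)
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("One-component sPLS model: %d/%d metabolites selected (eta = %g)\n",
              length(selected_metabolites(x)), length(x$weights), x$eta))
  if (!is.na(x$rmsecv))
    cat(sprintf("  RMSECV = %.3f, R2CV = %.3f\n", x$rmsecv, x$r2cv))
  invisible(x)
}
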
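# Independent oracles used to validate the implementation.  Each oracle
# takes a different computational route from the package code.

# One-component NIPALS PLS X-weights via mixOmics (established independent
# implementation); falls back to the textbook NIPALS iteration if mixOmics
# is unavailable.
nipals_weights <- function(Z, y) {
  if (requireNamespace("mixOmics", quietly = TRUE)) {
    fit <- mixOmics::pls(Z, y, ncomp = 1, mode = "regression",
                         scale = FALSE)
    return(as.numeric(fit$loadings$X[, 1]))
  }
  u <- y
  w <- rep(1 / sqrt(ncol(Z)), ncol(Z))
  for (i in 1:200) {
    w_new <- drop(crossprod(Z, u)); w_new <- w_new / sqrt(sum(w_new^2))
    t_sc <- drop(Z %*% w_new)
    u <- y * drop(crossprod(y, t_sc)) / sum(y^2)
    if (sum((w_new - w)^2) < 1e-16) { w <- w_new; break }
    w <- w_new
  }
  w
}

# Upper-tail hypergeometric by direct term-wise enumeration of the pmf
hyper_tail_enum <- function(N, K, n, k) {
  kk <- max(k, max(0, n - (N - K))):min(K, n)
  kk <- kk[kk >= k]
  if (length(kk) == 0) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# ACME for a linear mediator / logistic outcome model at the fitted point
# estimates, by numerical integration over the mediator's residual normal
# distribution on a fine grid (no simulation).
acme_numint <- function(mediator_fit, outcome_fit, exposure, treat, control,
                        grid_pts = 241, width = 7) {
  Xm <- model.matrix(mediator_fit)
  Xo <- model.matrix(outcome_fit)
  med_name <- all.vars(formula(mediator_fit))[1]
  sigma <- summary(mediator_fit)$sigma
  bm <- coef(mediator_fit); bo <- coef(outcome_fit)
  gq <- seq(-width, width, length.out = grid_pts)
  wq <- dnorm(gq); wq <- wq / sum(wq)

  mu_at <- function(a) { X <- Xm; X[, exposure] <- a; drop(X %*% bm) }
  # E over samples and mediator noise of the outcome probability at
  # exposure a, mediator drawn at exposure a_m
  p_bar <- function(a, a_m) {
    X <- Xo; X[, exposure] <- a
    mu <- mu_at(a_m)
    base <- drop(X %*% bo) - X[, med_name] * bo[med_name]
    acc <- 0
    for (q in seq_along(gq)) {
      m <- mu + sigma * gq[q]
      acc <- acc + wq[q] * mean(plogis(base + bo[med_name] * m))
    }
    acc
  }
  p_tt <- p_bar(treat, treat);  p_tc <- p_bar(treat, control)
  p_ct <- p_bar(control, treat); p_cc <- p_bar(control, control)
  list(acme = ((p_tt - p_tc) + (p_ct - p_cc)) / 2,
       ade  = ((p_tt - p_ct) + (p_tc - p_cc)) / 2,
       total = p_tt - p_cc)
}

# column-mean imputation baseline and masked-cell RMSE
mean_impute <- function(x) {
  cm <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- cm[j]
  x
}

masked_rmse <- function(imputed, truth, mask) {
  sqrt(mean((imputed[mask] - truth[mask])^2))
}

# one explicit sweep of column-wise RF prediction from the mean-initialised
# matrix, sharing the package's per-fit seed derivation (common random
# numbers make the comparison exact)
rf_one_sweep <- function(x, seed, num_trees = 100L) {
  miss <- is.na(x)
  imp <- mean_impute(x)
  n_miss <- colSums(miss)
  cols <- order(-n_miss, seq_len(ncol(x)))
  cols <- cols[n_miss[cols] > 0L]
  for (j in cols) {
    obs <- !miss[, j]
    xj <- imp[, -j, drop = FALSE]
    colnames(xj) <- paste0("V", seq_len(ncol(xj)))
    fit <- ranger::ranger(x = xj[obs, , drop = FALSE], y = imp[obs, j],
                          num.trees = num_trees,
                          seed = metabmi:::rf_fit_seed(seed, 1L, j),
                          num.threads = 1L)
    imp[!obs, j] <- predict(fit, data = xj[!obs, , drop = FALSE],
                            num.threads = 1L)$predictions
  }
  imp
}
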
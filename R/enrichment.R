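## Hypergeometric pathway over-representation
##
## Selected metabolites are tested for concentration in annotation
## sub-pathways against the background of metabolites available to the
## model, with one-sided (over-representation) hypergeometric p-values,
## fold enrichment, and BH-FDR plus Bonferroni control over the tested
## sub-pathways.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` pathway members among `n` selections drawn without
#' replacement from a background of `N` metabolites of which `K` belong to
#' the pathway.  Inclusive of the observed count; `k = 0` gives exactly 1.
#'
#' @param N background size.
#' @param K pathway size within the background.
#' @param n number of selected metabolites.
#' @param k observed selected-in-pathway count.
#' @return the one-sided p-value.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  N <- check_count(N, "N"); K <- check_count(K, "K")
  n <- check_count(n, "n"); k <- check_count(k, "k")
  if (K > N) stop_field("K", "must satisfy K <= N")
  if (n > N) stop_field("n", "must satisfy n <= N")
  if (k > min(K, n)) stop_field("k", "must satisfy k <= min(K, n)")
  if (k == 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @param m number of tests (defaults to `length(pvals)`).
#' @return q-values in the input order, capped at 1.
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0L) stop_field("pvals", "must be non-empty")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop_field("pvals", "must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Hypergeometric over-representation of selected metabolites
#'
#' One test per annotation sub-pathway with at least one selected member
#' (by default), comparing the observed selected-in-pathway count to its
#' expectation under random selection from the background.  Unannotated
#' background metabolites fall into an `"Unassigned"` sub-pathway.  The
#' multiplicity `m` for FDR and Bonferroni equals the number of tested rows
#' (set `test_all_pathways = TRUE` to test, and correct over, every
#' annotated sub-pathway).
#'
#' @param selected_ids metabolite ids selected by the model (non-empty,
#'   subset of the background).
#' @param annotation data.frame with columns `metabolite_id`, `sub_pathway`,
#'   `super_pathway`.
#' @param background_ids metabolites available to the model (defaults to all
#'   annotated metabolites).
#' @param test_all_pathways include sub-pathways with zero selected members.
#' @return data.frame of class `enrichment_table`, ordered by p:
#'   sub_pathway, super_pathway, K (pathway size), k (selected in pathway),
#'   n (selected total), N (background), expected, fold_enrichment
#'   (`(k/n)/(K/N)`), p, q_fdr, p_bonf.
#' @export
enrich <- function(selected_ids, annotation,
                   background_ids = annotation$metabolite_id,
                   test_all_pathways = FALSE) {
  if (length(selected_ids) == 0L)
    stop("`selected_ids` is empty; nothing to test", call. = FALSE)
  stopifnot(is.data.frame(annotation),
            all(c("metabolite_id", "sub_pathway") %in% names(annotation)))
  background_ids <- unique(background_ids)
  stray <- setdiff(selected_ids, background_ids)
  if (length(stray))
    stop(sprintf("selected metabolite(s) outside the background: %s",
                 paste(stray, collapse = ", ")), call. = FALSE)

  sub <- annotation$sub_pathway[match(background_ids, annotation$metabolite_id)]
  sub[is.na(sub) | sub == ""] <- "Unassigned"
  sup_map <- annotation$super_pathway[match(background_ids, annotation$metabolite_id)]
  sup_of <- tapply(ifelse(is.na(sup_map), "Unassigned", sup_map), sub,
                   function(v) v[1])

  N <- length(background_ids)
  n <- length(unique(selected_ids))
  K <- table(sub)
  sel_sub <- sub[background_ids %in% selected_ids]
  k <- table(factor(sel_sub, levels = names(K)))

  keep <- if (test_all_pathways) rep(TRUE, length(K)) else k >= 1L
  K <- as.integer(K[keep]); kk <- as.integer(k[keep])
  labels <- names(k)[keep]
  p <- mapply(hypergeom_upper_tail, N = N, K = K, n = n, k = kk)
  m <- length(p)
  out <- data.frame(sub_pathway = labels,
                    super_pathway = unname(sup_of[labels]),
                    K = K, k = kk, n = n, N = N,
                    expected = n * K / N,
                    fold_enrichment = (kk / n) / (K / N),
                    p = p,
                    q_fdr = bh_adjust(p, m),
                    p_bonf = pmin(1, p * m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$fold_enrichment), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
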
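#' @keywords internal
"_PACKAGE"

## Internal validation helpers -------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single number")
  ok <- if (open) x > lo && x < hi else x >= lo && x <= hi
  if (!ok)
    stop_field(field, sprintf("must lie in %s%g, %g%s",
                              if (open) "(" else "[", lo, hi,
                              if (open) ")" else "]"))
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

## Seed handling: every stochastic routine accepts `seed`; NULL leaves the
## global RNG untouched, an integer gives bit-for-bit reproducibility without
## clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out to one seed per stage through a fixed
#' affine map, so stages can be rerun independently yet reproducibly.
#'
#' @param seed integer global seed.
#' @param index non-negative stage counter.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, index) {
  seed <- check_count(seed, "seed")
  index <- check_count(index, "index")
  as.integer((as.double(seed) + 10007 * (index + 1)) %% 2147483629)
}

## z-score a vector, erroring on degenerate input
zscore <- function(v, field = "vector") {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop_field(field, "has zero variance; cannot standardize")
  (v - mean(v)) / s
}
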
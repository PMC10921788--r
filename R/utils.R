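# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Spearman rank correlation with average ranks
#'
#' Pairwise-complete Spearman correlation. Returns `NA` when fewer than
#' `min_n` complete pairs remain or when either variable has zero variance
#' (a rank correlation is undefined there, not zero).
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum number of complete pairs (default 3).
#' @return a single numeric in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' spearman_rho(c(0.1, 0.1, 0.3), c(0, 1, 2))
spearman_rho <- function(x, y, min_n = 3L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < min_n) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

#' Jaccard index between two sets
#'
#' `|A intersect B| / |A union B|`; 0 when the union is empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return numeric in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

# Gene symbols are upper-cased on ingest everywhere so GMT sets, expression
# rownames and genotype gene maps cannot disagree on case.
norm_genes <- function(x) toupper(trimws(x))

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
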
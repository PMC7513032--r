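# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("'%s' must be positive", name))
  if (integer && x != round(x))
    stop_invalid(sprintf("'%s' must be a whole number", name))
  invisible(x)
}

# Row-wise log-sum-exp of a matrix (numerically stable).
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Deterministic per-repeat seed derivation: one child stream per counter value,
# so adding repeats or conditions never shifts earlier draws.  All sub-seeds
# stay below 2^31 - 1.
derive_seeds <- function(master_seed, counter, n_seeds = 4L) {
  child <- (abs(as.numeric(master_seed)) + 999983 * as.numeric(counter)) %%
    2147483629
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(child))
  sample.int(2147483646L, n_seeds)
}

# Principal angles (radians) between the row spaces of two matrices with the
# same number of columns.  Used to compare fitted subspaces.

#' Principal angles between two row spaces
#'
#' Computes the principal angles (in radians, ascending) between the subspaces
#' spanned by the rows of `a` and the rows of `b`.  Invariant to invertible
#' row operations, so it compares subspaces rather than individual weight
#' vectors — the natural comparison for PCA/ICA solutions, which are only
#' identified up to permutation, sign and scale.
#'
#' @param a,b Numeric matrices with the same number of columns.
#' @return Numeric vector of `min(nrow(a), nrow(b))` angles in `[0, pi/2]`.
#' @export
principal_angles <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop_invalid("matrices must have the same number of columns")
  qa <- qr.Q(qr(t(a)))
  qb <- qr.Q(qr(t(b)))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}
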
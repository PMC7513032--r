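#' Coarse-graining grid
#'
#' Finite measurement resolution turning differential quantities into
#' non-negative discrete ones: every dimension is binned with a common width
#' `Delta` over `[lower, upper]`.  The `log Delta` offsets this induces are
#' carried explicitly by every estimator in the package so that the
#' information-accounting identities hold exactly.
#'
#' @param bin_width Positive common bin width `Delta`.
#' @param lower,upper Support bounds; `(upper - lower) / bin_width` must be an
#'   integer number of bins `>= 2`.
#' @param clip_policy What to do with samples outside the support:
#'   `"clip_to_edge"` (default; keeps probability mass normalised) or
#'   `"drop"`.
#' @return An object of class `coarse_graining`.
#' @export
coarse_graining <- function(bin_width = 0.1, lower = -6, upper = 6,
                            clip_policy = c("clip_to_edge", "drop")) {
  clip_policy <- match.arg(clip_policy)
  check_scalar_number(bin_width, "bin_width", positive = TRUE)
  check_scalar_number(lower, "lower")
  check_scalar_number(upper, "upper")
  if (upper <= lower) stop_invalid("need upper > lower")
  k <- (upper - lower) / bin_width
  if (abs(k - round(k)) > 1e-8 || round(k) < 2)
    stop_invalid("(upper - lower) / bin_width must be an integer >= 2")
  structure(list(bin_width = bin_width, lower = lower, upper = upper,
                 n_bins = as.integer(round(k)), clip_policy = clip_policy),
            class = "coarse_graining")
}

#' @export
print.coarse_graining <- function(x, ...) {
  cat(sprintf("<coarse_graining> Delta = %g on [%g, %g] (%d bins/dim, %s)\n",
              x$bin_width, x$lower, x$upper, x$n_bins, x$clip_policy))
  invisible(x)
}

# Map an n x d matrix to integer bin codes.  Returns the codes (one integer
# per retained row), the per-dimension index matrix, and the rows kept (for
# the "drop" policy).
bin_codes <- function(values, grid) {
  d <- ncol(values)
  k <- grid$n_bins
  idx <- floor((values - grid$lower) / grid$bin_width) + 1
  if (grid$clip_policy == "clip_to_edge") {
    idx <- pmin(pmax(idx, 1), k)
    keep <- rep(TRUE, nrow(values))
  } else {
    keep <- rowSums(idx >= 1 & idx <= k) == d
    idx <- idx[keep, , drop = FALSE]
  }
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = d)
  codes <- idx[, 1L]
  if (d > 1L) for (j in 2:d) codes <- codes + (idx[, j] - 1) * k^(j - 1)
  list(codes = codes, idx = idx, keep = keep)
}

# Decode packed codes back to bin centers (q x d matrix).
bin_centers <- function(codes, d, grid) {
  k <- grid$n_bins
  out <- matrix(0, length(codes), d)
  rem <- codes - 1
  for (j in seq_len(d)) {
    ij <- rem %% k
    out[, j] <- grid$lower + (ij + 0.5) * grid$bin_width
    rem <- (rem - ij) / k
  }
  out
}

#' Plug-in entropy of a binned sample
#'
#' Coarse-grained Shannon entropy `H = -sum_b phat_b log phat_b` of the
#' d-dimensional histogram of the batch on the grid, in nats.  Non-negative by
#' construction; zero exactly when every sample falls in a single bin.
#' Limited to `d <= 4` (higher-dimensional histograms are hopelessly sparse at
#' realistic sample sizes; use the quadrature marginal instead).
#'
#' @param batch A [sample_batch()] or numeric matrix.
#' @param grid A [coarse_graining()].
#' @return Entropy in nats.
#' @export
binned_entropy <- function(batch, grid) {
  v <- batch_values(batch)
  if (nrow(v) < 1L) stop_invalid("empty batch")
  if (!all(is.finite(v))) stop_invalid("batch must be finite")
  if (ncol(v) > 4L)
    stop_invalid("binned entropy supports at most 4 dimensions; ",
                 "use the quadrature backend for wider variables")
  bc <- bin_codes(v, grid)
  if (length(bc$codes) == 0L)
    stop_invalid("all samples were dropped as out of range")
  cnt <- rle(sort(bc$codes))$lengths
  p <- cnt / sum(cnt)
  -sum(p * log(p)) + 0      # + 0 normalises -0; exactly 0 for one bin
}

#' Convert nats to bits
#'
#' @param v Value(s) in nats.
#' @return `v / log(2)` in bits (1 nat = 1.4427 bits).
#' @export
nats_to_bits <- function(v) v / log(2)
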
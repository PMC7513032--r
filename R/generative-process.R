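#' Linear generative process of the external world
#'
#' Defines the world model `x = theta s + z`: `N` independent hidden sources
#' with zero mean and unit variance (Laplace, scale `1/sqrt(2)`, or standard
#' Gaussian), mixed into `M` sensory channels by the mixing matrix `theta`,
#' plus Gaussian background noise with covariance `Sigma_z`.
#'
#' @param mixing_matrix Numeric `M x N` mixing matrix (full column rank;
#'   a warning is issued otherwise).
#' @param source_family `"laplace"` or `"gaussian"`; either way the sources
#'   have zero mean and unit variance, so the Laplace scale is fixed at
#'   `1/sqrt(2)`.
#' @param noise_covariance Symmetric positive semi-definite `M x M` noise
#'   covariance.
#' @return An object of class `linear_generative_process` with fields
#'   `mixing_matrix`, `source_family`, `noise_covariance`, `input_dim` (M)
#'   and `source_dim` (N).
#' @seealso [make_random_process()], [simulate.linear_generative_process()]
#' @export
linear_generative_process <- function(mixing_matrix,
                                      source_family = c("laplace", "gaussian"),
                                      noise_covariance) {
  source_family <- match.arg(source_family)
  theta <- as.matrix(mixing_matrix)
  storage.mode(theta) <- "double"
  M <- nrow(theta); N <- ncol(theta)
  if (M < N || N < 1L)
    stop_invalid("need input_dim M >= source_dim N >= 1")
  sz <- as.matrix(noise_covariance)
  if (!isTRUE(all.equal(sz, t(sz), tolerance = 1e-10)) ||
      any(dim(sz) != M))
    stop_invalid("noise_covariance must be a symmetric M x M matrix")
  ev <- eigen(sz, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop_invalid("noise_covariance must be positive semi-definite")
  sv <- svd(theta, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-10 * max(sv))
    warning("mixing matrix is (numerically) column-rank deficient; ",
            "sources are not identifiable", call. = FALSE)
  structure(list(mixing_matrix = theta, source_family = source_family,
                 noise_covariance = sz, input_dim = M, source_dim = N),
            class = "linear_generative_process")
}

#' @export
print.linear_generative_process <- function(x, ...) {
  cat(sprintf(
    "<linear_generative_process> M = %d inputs, N = %d %s sources\n",
    x$input_dim, x$source_dim, x$source_family))
  invisible(x)
}

#' Draw a random linear generative process
#'
#' Mixing-matrix entries are i.i.d. standard normal with each column rescaled
#' to unit Euclidean norm (so every source injects unit signal energy); the
#' noise covariance is diagonal with per-channel variances drawn uniformly in
#' `[0.25, 1] * noise_scale^2`.  The default `noise_scale = 0.2` keeps noise
#' variance well below the unit source variance, the regime in which blind
#' source separation of the mixture is feasible.
#'
#' @param M,N Input and source dimensions, `M >= N >= 1`.
#' @param noise_scale Positive noise standard-deviation scale.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param source_family Source distribution, `"laplace"` (default) or
#'   `"gaussian"`.
#' @return A [linear_generative_process()].
#' @export
make_random_process <- function(M, N, noise_scale = 0.2, seed,
                                source_family = c("laplace", "gaussian")) {
  check_scalar_number(M, "M", positive = TRUE, integer = TRUE)
  check_scalar_number(N, "N", positive = TRUE, integer = TRUE)
  if (M < N) stop_invalid("need M >= N")
  check_scalar_number(noise_scale, "noise_scale", positive = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  source_family <- match.arg(source_family)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  theta <- matrix(stats::rnorm(M * N), M, N)
  theta <- sweep(theta, 2L, sqrt(colSums(theta^2)), "/")
  vars <- stats::runif(M, 0.25, 1) * noise_scale^2
  linear_generative_process(theta, source_family, diag(vars, M))
}

# Row-stable i.i.d. draws: row i of the returned n x d matrix depends only on
# the first i*d variates of the stream, so enlarging n extends a batch without
# changing earlier rows.
draw_source_matrix <- function(n, d, family) {
  if (family == "gaussian") {
    matrix(stats::rnorm(n * d), n, d, byrow = TRUE)
  } else {
    u <- stats::runif(n * d) - 0.5
    b <- 1 / sqrt(2)                       # variance 2 b^2 = 1
    matrix(-b * sign(u) * log1p(-2 * abs(u)), n, d, byrow = TRUE)
  }
}

#' Simulate sources and sensory inputs
#'
#' Draws `nsim` i.i.d. realisations of the hidden sources and of the sensory
#' inputs `x = theta s + z`.  Sources and noise consume independent seeded
#' substreams, so the first rows of a longer simulation coincide with a
#' shorter one under the same seed.
#'
#' @param object A [linear_generative_process()].
#' @param nsim Number of samples, `>= 1`.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return A list with `sources` (`nsim x N`) and `inputs` (`nsim x M`), both
#'   [sample_batch()] objects.
#' @export
simulate.linear_generative_process <- function(object, nsim = 1, seed = NULL,
                                               ...) {
  check_scalar_number(nsim, "nsim", positive = TRUE, integer = TRUE)
  if (is.null(seed)) stop_invalid("a seed is required")
  check_scalar_number(seed, "seed", integer = TRUE)
  M <- object$input_dim; N <- object$source_dim
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sub <- sample.int(2147483646L, 2L)
  set.seed(sub[1L])
  s <- draw_source_matrix(nsim, N, object$source_family)
  set.seed(sub[2L])
  sz <- object$noise_covariance
  if (all(sz == diag(diag(sz), M))) {          # diagonal fast path
    z <- matrix(stats::rnorm(nsim * M), nsim, M, byrow = TRUE)
    z <- sweep(z, 2L, sqrt(diag(sz)), "*")
  } else {
    ed <- eigen(sz, symmetric = TRUE)
    rt <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
    z <- matrix(stats::rnorm(nsim * M), nsim, M, byrow = TRUE) %*% rt
  }
  x <- tcrossprod(s, object$mixing_matrix) + z
  list(sources = sample_batch(s, "sources", as.integer(seed)),
       inputs  = sample_batch(x, "inputs",  as.integer(seed)))
}

#' Log density of the source distribution
#'
#' Per-point log of the factorised source density `prod_i p(s_i)`.  For the
#' Laplace family the scale is `1/sqrt(2)` (unit variance), giving
#' `sum_i (-log(2)/2 - sqrt(2) |s_i|)`; for the Gaussian family the standard
#' normal product.
#'
#' @param process A [linear_generative_process()].
#' @param points Numeric matrix `k x N` of evaluation points.
#' @return Numeric vector of `k` log densities.
#' @export
source_log_density <- function(process, points) {
  pts <- batch_values(points, width = process$source_dim, what = "points")
  if (!all(is.finite(pts))) stop_invalid("points must be finite")
  if (process$source_family == "laplace") {
    rowSums(-0.5 * log(2) - sqrt(2) * abs(pts))
  } else {
    rowSums(stats::dnorm(pts, log = TRUE))
  }
}

#' Write / read a generative process as plain text
#'
#' Serialises the dimensions, source family and the `theta` / `Sigma_z`
#' matrices to a single key/value + matrix-dump text file.
#'
#' @param process A [linear_generative_process()].
#' @param path File path.
#' @return `write_process()` returns `path` invisibly; `read_process()`
#'   returns the reconstructed process.
#' @export
write_process <- function(process, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("input_dim=%d", process$input_dim),
               sprintf("source_dim=%d", process$source_dim),
               sprintf("source_family=%s", process$source_family),
               "[mixing_matrix]",
               apply(format(process$mixing_matrix, digits = 17), 1L, paste,
                     collapse = " "),
               "[noise_covariance]",
               apply(format(process$noise_covariance, digits = 17), 1L, paste,
                     collapse = " ")), con)
  invisible(path)
}

#' @rdname write_process
#' @export
read_process <- function(path) {
  lines <- readLines(path)
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*", "", kv); vals <- sub("^[^=]*=", "", kv)
  getv <- function(k) vals[match(k, keys)]
  M <- as.integer(getv("input_dim")); N <- as.integer(getv("source_dim"))
  read_block <- function(tag, nr) {
    i <- match(tag, lines)
    do.call(rbind, lapply(lines[(i + 1L):(i + nr)], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]])))
  }
  linear_generative_process(read_block("[mixing_matrix]", M),
                            getv("source_family"),
                            read_block("[noise_covariance]", M))
}
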
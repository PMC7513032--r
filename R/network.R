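#' Linear neural network (recognition + generative model)
#'
#' Houses the network's internal parameters: the recognition (feedforward)
#' matrix `W` mapping inputs to outputs `u = W x`, the generative (feedback)
#' matrix `V` reconstructing inputs as `x = V u + eps`, and the model of the
#' reconstruction error: either a scalar precision `gamma` (error covariance
#' `gamma^-1 I`) or a full error covariance `Sigma_eps`.
#'
#' Outputs are treated as a deterministic function of the inputs (the network
#' settles to `u = W x` fast relative to the source dynamics); no output noise
#' is modelled.
#'
#' @param recognition_matrix Numeric `N x M` matrix `W`.
#' @param generative_matrix Numeric `M x N` matrix `V`.
#' @param error_precision Positive scalar `gamma` (used in
#'   `"scalar_precision"` mode).
#' @param error_cov_mode `"scalar_precision"` or `"full_covariance"`.
#' @param error_covariance Symmetric positive-definite `M x M` matrix,
#'   required in `"full_covariance"` mode.
#' @return An object of class `linear_network`.
#' @export
linear_network <- function(recognition_matrix, generative_matrix,
                           error_precision = 1,
                           error_cov_mode = c("scalar_precision",
                                              "full_covariance"),
                           error_covariance = NULL) {
  error_cov_mode <- match.arg(error_cov_mode)
  W <- as.matrix(recognition_matrix); V <- as.matrix(generative_matrix)
  storage.mode(W) <- "double"; storage.mode(V) <- "double"
  N <- nrow(W); M <- ncol(W)
  if (nrow(V) != M || ncol(V) != N)
    stop_invalid("generative matrix must be the transpose shape (M x N) of W")
  check_scalar_number(error_precision, "error_precision", positive = TRUE)
  if (error_cov_mode == "full_covariance") {
    if (is.null(error_covariance))
      stop_invalid("full_covariance mode needs an error_covariance")
    error_covariance <- as.matrix(error_covariance)
    if (any(dim(error_covariance) != M) ||
        !isTRUE(all.equal(error_covariance, t(error_covariance),
                          tolerance = 1e-8)))
      stop_invalid("error_covariance must be a symmetric M x M matrix")
    ev <- eigen(error_covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_invalid("error_covariance must be positive definite")
  }
  structure(list(recognition_matrix = W, generative_matrix = V,
                 error_precision = error_precision,
                 error_cov_mode = error_cov_mode,
                 error_covariance = error_covariance,
                 input_dim = M, output_dim = N),
            class = "linear_network")
}

#' @export
print.linear_network <- function(x, ...) {
  cat(sprintf("<linear_network> %d -> %d, %s", x$input_dim, x$output_dim,
              x$error_cov_mode))
  if (x$error_cov_mode == "scalar_precision")
    cat(sprintf(" (gamma = %.4g)", x$error_precision))
  cat("\n")
  invisible(x)
}

#' Output prior specification
#'
#' The factorised prior `p0(u) = prod_i p0(u_i)` the network expects its
#' outputs to follow.  `"flat"` priors contribute only constants and are not
#' evaluable.
#'
#' @param family `"laplace"`, `"gaussian"` or `"flat"`.
#' @param variance Positive prior variance (per dimension); ignored for flat.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("laplace", "gaussian", "flat"),
                       variance = 1) {
  family <- match.arg(family)
  if (family != "flat")
    check_scalar_number(variance, "variance", positive = TRUE)
  structure(list(family = family, variance = variance), class = "prior_spec")
}

#' Apply the recognition model
#'
#' Maps a batch of sensory inputs through `u = W x`, row by row.
#'
#' @param network A [linear_network()].
#' @param inputs Inputs batch of width `M`.
#' @return A [sample_batch()] of outputs, width `N`, row-aligned with inputs.
#' @export
recognize <- function(network, inputs) {
  x <- batch_values(inputs, width = network$input_dim, what = "inputs")
  sample_batch(tcrossprod(x, network$recognition_matrix), "outputs",
               if (inherits(inputs, "sample_batch")) inputs$seed else NULL)
}

#' Reconstruction errors of the generative model
#'
#' Computes `eps = x - V u` for row-aligned batches of inputs and outputs.
#'
#' @param inputs Inputs batch, width `M`.
#' @param outputs Outputs batch, width `N` (same number of rows).
#' @param network A [linear_network()].
#' @return A [sample_batch()] of errors, width `M`.
#' @export
reconstruction_error <- function(inputs, outputs, network) {
  x <- batch_values(inputs, width = network$input_dim, what = "inputs")
  u <- batch_values(outputs, width = network$output_dim, what = "outputs")
  if (nrow(x) != nrow(u))
    stop_invalid("inputs and outputs must have the same number of rows")
  sample_batch(x - tcrossprod(u, network$generative_matrix), "errors")
}

#' Coarse-grained model log likelihood
#'
#' Per-row value of `log(p*(x | u) Delta_x)` under the Gaussian likelihood,
#' evaluated from the reconstruction errors.  In scalar-precision mode this is
#' `-(gamma/2) eps' eps + (M/2) log gamma - (M/2) log 2 pi + M log Delta`; in
#' full-covariance mode the corresponding multivariate normal form.  All
#' constants (including the binning offset `M log Delta`) are kept explicit so
#' that the information-accounting identities hold exactly downstream.
#'
#' @param errors Errors batch, width `M`.
#' @param network A [linear_network()].
#' @param grid A [coarse_graining()] supplying the resolution `Delta`.
#' @return Numeric vector, one value per row.
#' @export
model_log_likelihood <- function(errors, network, grid) {
  e <- batch_values(errors, width = network$input_dim, what = "errors")
  M <- network$input_dim
  log_delta <- M * log(grid$bin_width)
  if (network$error_cov_mode == "scalar_precision") {
    g <- network$error_precision
    -(g / 2) * rowSums(e^2) + (M / 2) * log(g) - (M / 2) * log(2 * pi) +
      log_delta
  } else {
    se <- network$error_covariance
    ch <- chol(se)
    w <- backsolve(ch, t(e), transpose = TRUE)   # ch' w = e'
    -0.5 * colSums(w^2) - sum(log(diag(ch))) - (M / 2) * log(2 * pi) +
      log_delta
  }
}

#' Log density of outputs under a factorised prior
#'
#' Per-row `sum_i log p0(u_i)`.  The Laplace family uses scale
#' `sqrt(variance / 2)` so the prior variance is as specified.
#'
#' @param outputs Outputs batch.
#' @param prior A non-flat [prior_spec()].
#' @return Numeric vector, one value per row.
#' @export
prior_log_density <- function(outputs, prior) {
  if (prior$family == "flat")
    stop_invalid("flat priors contribute constants only and cannot be ",
                 "evaluated")
  u <- batch_values(outputs, what = "outputs")
  if (prior$family == "laplace") {
    b <- sqrt(prior$variance / 2)
    rowSums(-log(2 * b) - abs(u) / b)
  } else {
    sd <- sqrt(prior$variance)
    rowSums(stats::dnorm(u, sd = sd, log = TRUE))
  }
}

#' Set the error covariance from data (fine-tuned mode)
#'
#' Switches a network to `full_covariance` mode with `Sigma_eps` equal to the
#' empirical covariance of the current reconstruction errors (plus a small
#' diagonal ridge for invertibility) — the fine-tuned error model under which
#' the free-energy expectation reduces to the prior-divergence part alone.
#'
#' @param network A [linear_network()].
#' @param inputs Inputs batch used to measure the errors.
#' @param ridge Diagonal ridge added for invertibility.
#' @return The updated [linear_network()].
#' @export
finetune_error_covariance <- function(network, inputs, ridge = 1e-8) {
  u <- recognize(network, inputs)
  e <- batch_values(reconstruction_error(inputs, u, network))
  se <- crossprod(e) / nrow(e) + diag(ridge, network$input_dim)
  linear_network(network$recognition_matrix, network$generative_matrix,
                 network$error_precision, "full_covariance", se)
}

#' Write / read a network as plain text
#'
#' @param network A [linear_network()].
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()` the
#'   reconstructed network.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w"); on.exit(close(con))
  lines <- c(sprintf("input_dim=%d", network$input_dim),
             sprintf("output_dim=%d", network$output_dim),
             sprintf("error_cov_mode=%s", network$error_cov_mode),
             sprintf("error_precision=%.17g", network$error_precision),
             "[recognition_matrix]",
             apply(format(network$recognition_matrix, digits = 17), 1L,
                   paste, collapse = " "),
             "[generative_matrix]",
             apply(format(network$generative_matrix, digits = 17), 1L,
                   paste, collapse = " "))
  if (network$error_cov_mode == "full_covariance")
    lines <- c(lines, "[error_covariance]",
               apply(format(network$error_covariance, digits = 17), 1L,
                     paste, collapse = " "))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*", "", kv); vals <- sub("^[^=]*=", "", kv)
  getv <- function(k) vals[match(k, keys)]
  M <- as.integer(getv("input_dim")); N <- as.integer(getv("output_dim"))
  mode <- getv("error_cov_mode")
  read_block <- function(tag, nr) {
    i <- match(tag, lines)
    do.call(rbind, lapply(lines[(i + 1L):(i + nr)], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]])))
  }
  linear_network(read_block("[recognition_matrix]", N),
                 read_block("[generative_matrix]", M),
                 as.numeric(getv("error_precision")), mode,
                 if (mode == "full_covariance")
                   read_block("[error_covariance]", M) else NULL)
}
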
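#' Mutual information between inputs and internal states
#'
#' The outputs are a deterministic function of the inputs (`u = W x`), so the
#' conditional output entropy is taken as zero and the information the network
#' stores about its inputs is `I[x; phi] = H[u]`; the conditional input
#' entropy follows as `H[x | phi] = H[x] - H[u]`.  The decomposition
#' `I = H[x] - H[x|phi]` then holds exactly by construction.
#'
#' `H[u]` comes from an N-dimensional histogram (`backend = "histogram"`) or
#' from the quadrature marginal (`backend = "quadrature"`); `H[x]` always uses
#' the quadrature marginal (an M-dimensional histogram cannot be populated at
#' realistic sample sizes), as the Monte-Carlo average of the negated
#' coarse-grained log density over an evenly spaced subsample of `n_eval`
#' rows.
#'
#' @param process A [linear_generative_process()].
#' @param network A [linear_network()].
#' @param inputs Inputs batch (width `M`).
#' @param outputs Outputs batch, `recognize(network, inputs)`.
#' @param grid A [coarse_graining()].
#' @param backend `"histogram"` or `"quadrature"`.
#' @param n_eval Number of rows used for Monte-Carlo quadrature averages.
#' @param H_x Optional precomputed `H[x]` (skips the quadrature pass).
#' @return List with `I_x_phi`, `H_x`, `H_x_given_phi`, and `H_u`.
#' @export
mutual_information <- function(process, network, inputs, outputs, grid,
                               backend = c("histogram", "quadrature"),
                               n_eval = 4000L, H_x = NULL) {
  backend <- match.arg(backend)
  x <- batch_values(inputs, width = network$input_dim, what = "inputs")
  u <- batch_values(outputs, width = network$output_dim, what = "outputs")
  if (nrow(x) != nrow(u))
    stop_invalid("inputs and outputs must have the same number of rows")
  idx <- eval_subsample(nrow(x), n_eval)
  if (is.null(H_x))
    H_x <- mean(-quadrature_log_marginal(process, NULL,
                                         x[idx, , drop = FALSE], grid))
  H_u <- if (backend == "histogram") {
    binned_entropy(u, grid)
  } else {
    mean(-quadrature_log_marginal(process, network$recognition_matrix,
                                  u[idx, , drop = FALSE], grid))
  }
  list(I_x_phi = H_u, H_x = H_x, H_x_given_phi = H_x - H_u, H_u = H_u)
}

# Deterministic evenly spaced subsample of row indices.
eval_subsample <- function(n, n_eval) {
  if (n <= n_eval) seq_len(n)
  else unique(round(seq(1, n, length.out = n_eval)))
}

#' Reconstruction cost L_X
#'
#' Mean coarse-grained negative log likelihood of the inputs under the
#' generative model, `L_X = <-log(p*(x|phi) Delta_x)>`.  In scalar-precision
#' mode this equals `(gamma/2) <eps' eps> - (M/2) log gamma +
#' (M/2) log 2 pi - M log Delta`.
#'
#' @param errors Errors batch (width `M`).
#' @param network A [linear_network()].
#' @param grid A [coarse_graining()].
#' @return `L_X` in nats.
#' @export
reconstruction_cost <- function(errors, network, grid) {
  mean(-model_log_likelihood(errors, network, grid))
}

#' Prior divergence L_A
#'
#' Kullback-Leibler divergence between the actual output distribution and the
#' factorised output prior — the ICA part of the free-energy expectation.
#' The histogram backend compares binned output frequencies against the prior
#' bin mass `p0(center) Delta^N` (empty bins contribute zero); the quadrature
#' backend averages `log p_u(u) - log p0(u)` with `p_u` from
#' [quadrature_log_marginal()] over an `n_eval` subsample.  The returned
#' value is floored at zero; the raw estimate is kept in attribute `"raw"`.
#'
#' @param process A [linear_generative_process()] (used by the quadrature
#'   backend).
#' @param network A [linear_network()] (its `W` defines the output
#'   projection).
#' @param outputs Outputs batch (width `N`).
#' @param prior A non-flat [prior_spec()].
#' @param grid A [coarse_graining()].
#' @param backend `"histogram"` or `"quadrature"`.
#' @param n_eval Subsample size for the quadrature backend.
#' @return `L_A` in nats (non-negative; attribute `"raw"` holds the unfloored
#'   estimate).
#' @export
prior_divergence <- function(process, network, outputs, prior, grid,
                             backend = c("histogram", "quadrature"),
                             n_eval = 4000L) {
  backend <- match.arg(backend)
  if (prior$family == "flat")
    stop_invalid("the prior divergence is undefined for flat priors")
  u <- batch_values(outputs, what = "outputs")
  d <- ncol(u)
  if (backend == "histogram") {
    bc <- bin_codes(u, grid)
    r <- rle(sort(bc$codes))
    phat <- r$lengths / sum(r$lengths)
    centers <- bin_centers(r$values, d, grid)
    logq <- prior_log_density(centers, prior) + d * log(grid$bin_width)
    raw <- sum(phat * (log(phat) - logq))
  } else {
    idx <- eval_subsample(nrow(u), n_eval)
    us <- u[idx, , drop = FALSE]
    lpu <- quadrature_log_marginal(process, network$recognition_matrix, us,
                                   grid)
    lq <- prior_log_density(us, prior) + d * log(grid$bin_width)
    raw <- mean(lpu - lq)
  }
  structure(max(raw, 0), raw = raw)
}

#' Assemble an information report
#'
#' Combines one evaluation's measures into the accounting identities of the
#' framework: utilizable information `X = H[x] - L_X - L_A` (the information
#' actually available for inference) and the free-energy expectation
#' `F_bar = I - X` (equivalently `L_X + L_A - H[x|phi]`) — the gap between
#' stored and utilizable information.  The identities hold exactly by
#' construction.  Also records the approximation `F_approx = L_X + L_A`,
#' which drops the conditional-entropy term.
#'
#' @param H_x,I_x_phi,H_x_given_phi Entropy, mutual information and
#'   conditional entropy in nats (from [mutual_information()]).
#' @param L_X Reconstruction cost (from [reconstruction_cost()]).
#' @param L_A Prior divergence (from [prior_divergence()]).
#' @param n_samples Number of samples behind the evaluation.
#' @param backend Estimator backend used (`"histogram"` or `"quadrature"`).
#' @return An object of class `info_report`.
#' @export
assemble_report <- function(H_x, I_x_phi, H_x_given_phi, L_X, L_A,
                            n_samples, backend = "histogram") {
  for (v in list(H_x, I_x_phi, H_x_given_phi, L_X, L_A))
    check_scalar_number(as.numeric(v), "report component")
  check_scalar_number(n_samples, "n_samples", positive = TRUE, integer = TRUE)
  if (abs(I_x_phi - (H_x - H_x_given_phi)) > 1e-9 * max(1, abs(H_x)))
    stop_invalid("inconsistent components: I must equal H_x - H_x_given_phi")
  X_util <- H_x - as.numeric(L_X) - as.numeric(L_A)
  structure(list(H_x = H_x, H_x_given_phi = H_x_given_phi,
                 I_x_phi = I_x_phi, L_X = as.numeric(L_X),
                 L_A = as.numeric(L_A), X_util = X_util,
                 F_bar = I_x_phi - X_util,
                 F_approx = as.numeric(L_X) + as.numeric(L_A),
                 n_samples = as.integer(n_samples), backend = backend),
            class = "info_report")
}

#' @export
print.info_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<info_report> (%s backend, n = %d) [nats]\n",
    "  H[x] = %.4f   H[x|phi] = %.4f   I[x;phi] = %.4f\n",
    "  L_X  = %.4f   L_A      = %.4f\n",
    "  X[x;phi] = %.4f   F_bar = %.4f   (F_approx = %.4f)\n"),
    x$backend, x$n_samples, x$H_x, x$H_x_given_phi, x$I_x_phi,
    x$L_X, x$L_A, x$X_util, x$F_bar, x$F_approx))
  invisible(x)
}

#' @export
as.data.frame.info_report <- function(x, ...) {
  data.frame(H_x = x$H_x, H_x_given_phi = x$H_x_given_phi,
             I_x_phi = x$I_x_phi, L_X = x$L_X, L_A = x$L_A,
             X_util = x$X_util, F_bar = x$F_bar, F_approx = x$F_approx,
             n_samples = x$n_samples, backend = x$backend)
}

#' Closed-form Gaussian entropies, surprise and free energy
#'
#' For Gaussian sources and a Gaussian output prior every quantity has a
#' closed form.  The input marginals are `p(x) = N(0, theta theta' + Sigma_z)`
#' and `p*(x) = N(0, v V V' + Sigma_eps)` (`v` the prior variance), giving the
#' surprise expectation `S_bar = KL[p(x) || p*(x)]`.
#'
#' Two free-energy conventions are returned.  `F_bar` is the exact joint
#' divergence with a width-matched Gaussian recognition density: the
#' recognition map contributes `1/2 <(Wx - Gx)' Sigma_post^-1 (Wx - Gx)>`,
#' where `G = v V'(v V V' + Sigma_eps)^-1` is the Bayes-optimal recognition
#' matrix and `Sigma_post` the model posterior covariance; hence
#' `F_bar >= S_bar >= 0` analytically, with equality to zero exactly when the
#' generative model and recognition matrix match the true process.
#' `F_bar_report` is the coarse-grained decomposition convention used by
#' [assemble_report()] (`L_X + L_A - H[x|phi]`, each term closed-form), which
#' carries the binning offsets and is directly comparable with the sampling
#' backends.
#'
#' @param process A Gaussian-source [linear_generative_process()].
#' @param network A [linear_network()].
#' @param grid A [coarse_graining()].
#' @param prior A Gaussian [prior_spec()] (default unit variance).
#' @return List with `H_x`, `S_bar`, `F_bar`, plus the decomposition terms
#'   `H_u`, `L_X`, `L_A` and `F_bar_report`.
#' @export
gaussian_closed_form <- function(process, network, grid,
                                 prior = prior_spec("gaussian", 1)) {
  if (process$source_family != "gaussian")
    stop_invalid("closed forms require Gaussian sources")
  if (prior$family != "gaussian")
    stop_invalid("closed forms require a Gaussian prior")
  M <- process$input_dim; N <- network$output_dim
  v <- prior$variance
  theta <- process$mixing_matrix
  W <- network$recognition_matrix; V <- network$generative_matrix
  sigma_x <- tcrossprod(theta) + process$noise_covariance
  sigma_eps <- if (network$error_cov_mode == "scalar_precision")
    diag(1 / network$error_precision, M) else network$error_covariance
  sigma_x_star <- v * tcrossprod(V) + sigma_eps

  ld <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)
  delta <- grid$bin_width

  H_x <- 0.5 * (M * log(2 * pi * exp(1)) + ld(sigma_x)) - M * log(delta)
  S_bar <- 0.5 * (sum(diag(solve(sigma_x_star, sigma_x))) - M -
                    ld(sigma_x) + ld(sigma_x_star))

  G <- v * t(V) %*% solve(sigma_x_star)
  sigma_post <- solve(diag(1 / v, N) + t(V) %*% solve(sigma_eps, V))
  D <- W - G
  F_bar <- S_bar +
    0.5 * sum(diag(solve(sigma_post, D %*% tcrossprod(sigma_x, D))))

  sigma_u <- W %*% tcrossprod(sigma_x, W)
  H_u <- 0.5 * (N * log(2 * pi * exp(1)) + ld(sigma_u)) - N * log(delta)
  IVW <- diag(M) - V %*% W
  sigma_e <- IVW %*% tcrossprod(sigma_x, IVW)
  L_X <- if (network$error_cov_mode == "scalar_precision") {
    g <- network$error_precision
    (g / 2) * sum(diag(sigma_e)) - (M / 2) * log(g) +
      (M / 2) * log(2 * pi) - M * log(delta)
  } else {
    0.5 * sum(diag(solve(sigma_eps, sigma_e))) + 0.5 * ld(sigma_eps) +
      (M / 2) * log(2 * pi) - M * log(delta)
  }
  L_A <- 0.5 * (sum(diag(sigma_u)) / v - N - ld(sigma_u) + N * log(v))
  list(H_x = H_x, S_bar = S_bar, F_bar = F_bar,
       H_u = H_u, L_X = L_X, L_A = L_A,
       F_bar_report = L_X + L_A - (H_x - H_u))
}

#' Matched Gaussian network
#'
#' Builds the network whose generative model exactly equals an all-Gaussian
#' process with `M = N`: generative matrix equal to the true mixing matrix,
#' full error covariance equal to the true noise covariance, and recognition
#' matrix equal to the Bayes-optimal map `v V'(v V V' + Sigma_eps)^-1` under a
#' unit-variance (or `prior`-variance) Gaussian output prior.  For this
#' network [gaussian_closed_form()] gives `S_bar = F_bar = 0`.
#'
#' @param process A Gaussian [linear_generative_process()] with `M = N`.
#' @param prior A Gaussian [prior_spec()].
#' @return A [linear_network()].
#' @export
matched_network <- function(process, prior = prior_spec("gaussian", 1)) {
  if (process$input_dim != process$source_dim)
    stop_invalid("the matched construction needs M = N")
  V <- process$mixing_matrix
  sigma_eps <- process$noise_covariance
  v <- prior$variance
  W <- v * t(V) %*% solve(v * tcrossprod(V) + sigma_eps)
  linear_network(W, V, error_cov_mode = "full_covariance",
                 error_covariance = sigma_eps)
}

#' Infomax objective for a linear network
#'
#' The mutual information between inputs and squashed outputs reduces, for the
#' linear system with `V = W'`, to `-log |det(I - W'W)| + <|u|^2>/2` up to
#' constants.  The determinant is singular exactly at row-orthonormal `W`;
#' a small ridge `eta` (the finite resolution at which `W` itself is measured)
#' regularises it, so the first term is maximal at orthonormal rows and the
#' second drives the outputs toward the dominant input subspace.
#'
#' @param network A [linear_network()].
#' @param outputs Outputs batch.
#' @param eta Positive regulariser added to the diagonal.
#' @return Objective value in nats (to be maximised).
#' @export
infomax_objective <- function(network, outputs, eta = 1e-3) {
  check_scalar_number(eta, "eta", positive = TRUE)
  u <- batch_values(outputs, width = network$output_dim, what = "outputs")
  W <- network$recognition_matrix
  A <- diag(network$input_dim) - crossprod(W) + diag(eta, network$input_dim)
  dt <- determinant(A, logarithm = TRUE)
  if (!is.finite(dt$modulus))
    stop("regularised determinant is singular", call. = FALSE)
  -as.numeric(dt$modulus) + mean(rowSums(u^2)) / 2
}
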
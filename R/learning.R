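#' Optimiser settings
#'
#' @param learning_rate Positive step size for gradient updates.
#' @param max_iterations Maximum number of iterations.
#' @param batch_size Rows per update; `Inf` (default) uses the full batch.
#' @param tolerance Relative objective-change stopping tolerance.
#' @param seed Integer seed for random initialisation.
#' @param gamma_schedule `"optimize"` (closed-form precision update each
#'   iteration, the default), `"fixed"` (hold `gamma_initial`), or `"anneal"`
#'   (geometric schedule from `gamma_initial` to `gamma_final`).
#' @param gamma_initial,gamma_final Precision values for the fixed/anneal
#'   schedules.
#' @param init `"pca"` (whitened principal subspace, default) or `"random"`.
#' @param recon_weight Relative weight of the reconstruction gradient in the
#'   encoder update.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(learning_rate = 0.1, max_iterations = 2000L,
                       batch_size = Inf, tolerance = 1e-8, seed = 1L,
                       gamma_schedule = c("optimize", "fixed", "anneal"),
                       gamma_initial = 1, gamma_final = 1,
                       init = c("pca", "random"), recon_weight = 1) {
  gamma_schedule <- match.arg(gamma_schedule)
  init <- match.arg(init)
  check_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  check_scalar_number(max_iterations, "max_iterations", positive = TRUE,
                      integer = TRUE)
  check_scalar_number(tolerance, "tolerance", positive = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  check_scalar_number(gamma_initial, "gamma_initial", positive = TRUE)
  check_scalar_number(gamma_final, "gamma_final", positive = TRUE)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 batch_size = batch_size, tolerance = tolerance,
                 seed = as.integer(seed), gamma_schedule = gamma_schedule,
                 gamma_initial = gamma_initial, gamma_final = gamma_final,
                 init = init, recon_weight = recon_weight),
            class = "fit_config")
}

# Empirical second-moment matrix (the model assumes zero-mean inputs).
input_second_moment <- function(x) crossprod(x) / nrow(x)

# gamma that minimises L_X for a given mean squared error.
optimal_gamma <- function(M, mean_sq_err) M / mean_sq_err

#' Fit a PCA network
#'
#' Finds the `N`-dimensional principal subspace of the inputs, the solution of
#' both the infomax objective and the least-mean-square reconstruction cost
#' under the tied-weights constraint `V = W'`.  `"closed_form"` takes the top
#' `N` unit eigenvectors of the empirical input second-moment matrix
#' (descending eigenvalue order, each row's largest-magnitude entry made
#' positive); `"oja"` runs Oja's subspace rule
#' `dW = lr * (<u x'> - <u u'> W)` from a random start.  Either way the
#' returned network has `V = W'` and scalar precision `gamma = M / <eps'eps>`.
#'
#' @param inputs Inputs batch (width `M > N`).
#' @param N Output dimension.
#' @param method `"closed_form"` or `"oja"`.
#' @param config A [fit_config()] (used by `"oja"`).
#' @return A [linear_network()].
#' @export
fit_pca <- function(inputs, N, method = c("closed_form", "oja"),
                    config = fit_config()) {
  method <- match.arg(method)
  x <- batch_values(inputs, what = "inputs")
  M <- ncol(x)
  check_scalar_number(N, "N", positive = TRUE, integer = TRUE)
  if (N >= M) stop_invalid("need N < M for dimensionality reduction")
  cx <- input_second_moment(x)
  if (method == "closed_form") {
    ed <- eigen(cx, symmetric = TRUE)
    W <- t(ed$vectors[, seq_len(N), drop = FALSE])
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    W <- matrix(stats::rnorm(N * M, sd = 0.1), N, M)
    lr <- config$learning_rate
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(config$max_iterations)) {
      WC <- W %*% cx
      W <- W + lr * (WC - tcrossprod(WC, W) %*% W)
      obj <- sum(diag(cx)) - sum(diag(tcrossprod(W %*% cx, W)))  # resid. var
      if (is.finite(prev) &&
          abs(prev - obj) <= config$tolerance * max(abs(prev), 1e-12)) {
        converged <- TRUE
        break
      }
      prev <- obj
    }
    if (!converged)
      warning("Oja's rule did not reach the tolerance; returning the last ",
              "iterate", call. = FALSE)
  }
  # sign convention: make each row's largest-magnitude entry positive
  sgn <- apply(W, 1L, function(r) sign(r[which.max(abs(r))]))
  W <- W * ifelse(sgn == 0, 1, sgn)
  resid <- x - x %*% crossprod(W)        # eps = (I - W'W) x
  gamma <- optimal_gamma(M, mean(rowSums(resid^2)))
  linear_network(W, t(W), gamma)
}

# Score function -d log p0 / du of the unit-scale prior families.
prior_score <- function(u, prior) {
  if (prior$family == "laplace") {
    b <- sqrt(prior$variance / 2)
    sign(u) / b
  } else if (prior$family == "gaussian") {
    u / prior$variance
  } else stop_invalid("flat priors have no score function")
}

#' Fit a network by free-energy minimisation
#'
#' Minimises the free-energy objective `L_X + L_A` over the recognition
#' matrix `W`, the generative matrix `V`, and the error precision, by
#' alternating exact minimisation with natural-gradient encoder steps:
#'
#' * decoder: `V <-` least-squares regression of `x` on `u` (exact);
#' * precision: `gamma <- M / <eps'eps>` (scalar mode) or
#'   `Sigma_eps <- <eps eps'>` plus a ridge (full mode) — exact;
#' * encoder: `W <- W + lr * ((I - <score(u) u'>) W +
#'   recon_weight * gamma V' <eps x'>)`, Amari's natural-gradient ICA rule
#'   plus the reconstruction gradient.
#'
#' The recorded trajectory tracks `L_X` (without the binning constant) and
#' the prior cross-entropy `<-log p0(u)>`; their sum is the optimisation
#' objective up to the output entropy, which the decoder/precision steps do
#' not change — so `objective_decoder[t] <= objective_encoder[t-1]` holds
#' exactly.
#'
#' @param inputs Inputs batch (width `M > N`).
#' @param N Output dimension.
#' @param prior A Laplace or Gaussian [prior_spec()].
#' @param config A [fit_config()].
#' @param error_cov_mode `"scalar_precision"` (default) or
#'   `"full_covariance"` (the fine-tuned error model).
#' @return A [linear_network()] with attribute `"trajectory"` (a data frame
#'   with columns `iteration`, `L_X`, `prior_ce`, `objective_decoder`,
#'   `objective_encoder`).
#' @export
fit_fep <- function(inputs, N, prior = prior_spec("laplace", 1),
                    config = fit_config(),
                    error_cov_mode = c("scalar_precision",
                                       "full_covariance")) {
  error_cov_mode <- match.arg(error_cov_mode)
  if (!prior$family %in% c("laplace", "gaussian"))
    stop_invalid("fit_fep needs a Laplace or Gaussian prior")
  x <- batch_values(inputs, what = "inputs")
  M <- ncol(x); n <- nrow(x)
  check_scalar_number(N, "N", positive = TRUE, integer = TRUE)
  if (N >= M) stop_invalid("need N < M")
  cx <- input_second_moment(x)

  ed <- eigen(cx, symmetric = TRUE)
  if (ed$values[N] <= 1e-12 * ed$values[1L])
    stop_invalid("input second-moment matrix is rank deficient in the ",
                 "requested subspace")
  if (config$init == "pca") {
    W <- diag(sqrt(prior$variance / ed$values[seq_len(N)]), N) %*%
      t(ed$vectors[, seq_len(N), drop = FALSE])      # whitened principal axes
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    W <- matrix(stats::rnorm(N * M, sd = 1 / sqrt(M)), N, M)
  }

  lr <- config$learning_rate
  lam <- config$recon_weight
  sched <- config$gamma_schedule
  gamma <- config$gamma_initial
  sigma_eps <- NULL
  traj <- vector("list", config$max_iterations)
  obj_enc_prev <- NA_real_
  V_old <- NULL; gamma_old <- NULL; sig_old <- NULL
  prev_obj <- Inf
  it_done <- 0L

  lx_of <- function(V, W, gamma, sig) {
    IVW <- diag(M) - V %*% W
    se <- IVW %*% tcrossprod(cx, IVW)
    if (error_cov_mode == "scalar_precision")
      (gamma / 2) * sum(diag(se)) - (M / 2) * log(gamma) +
        (M / 2) * log(2 * pi)
    else
      0.5 * sum(diag(solve(sig, se))) +
        0.5 * as.numeric(determinant(sig, logarithm = TRUE)$modulus) +
        (M / 2) * log(2 * pi)
  }

  for (it in seq_len(config$max_iterations)) {
    u <- x %*% t(W)
    ce <- mean(-prior_log_density(u, prior))
    if (it > 1L)
      traj[[it - 1L]]$objective_encoder <-
        lx_of(V_old, W, gamma_old, sig_old) + ce

    # decoder: exact least squares of x on u
    su <- W %*% tcrossprod(cx, W)
    sxu <- tcrossprod(cx, W)
    V <- t(solve(su, t(sxu)))
    IVW <- diag(M) - V %*% W
    se <- IVW %*% tcrossprod(cx, IVW)

    # precision / error covariance: exact closed form (or schedule)
    if (error_cov_mode == "full_covariance") {
      sigma_eps <- (se + t(se)) / 2 + diag(1e-8, M)
    } else {
      gamma <- switch(sched,
        optimize = optimal_gamma(M, sum(diag(se))),
        fixed = config$gamma_initial,
        anneal = config$gamma_initial *
          (config$gamma_final / config$gamma_initial)^
            ((it - 1) / max(config$max_iterations - 1, 1)))
    }
    L_X <- lx_of(V, W, gamma, sigma_eps)
    obj <- L_X + ce
    if (!is.finite(obj))
      stop(sprintf("free-energy objective diverged at iteration %d", it),
           call. = FALSE)
    traj[[it]] <- list(iteration = it, L_X = L_X, prior_ce = ce,
                       objective_decoder = obj, objective_encoder = NA_real_)
    it_done <- it
    if (is.finite(prev_obj) &&
        abs(prev_obj - obj) <= config$tolerance * max(abs(prev_obj), 1e-12))
      break
    prev_obj <- obj
    V_old <- V; gamma_old <- gamma; sig_old <- sigma_eps

    # encoder: natural-gradient ICA step + reconstruction gradient
    score_u <- prior_score(u, prior)
    C <- crossprod(score_u, u) / n
    prec_term <- if (error_cov_mode == "scalar_precision")
      gamma * t(V) else t(solve(sigma_eps, V))
    grad <- (diag(N) - C) %*% W + lam * prec_term %*% (IVW %*% cx)
    W <- W + lr * grad
    if (!all(is.finite(W)))
      stop(sprintf("encoder weights diverged at iteration %d", it),
           call. = FALSE)
  }

  traj <- do.call(rbind, lapply(traj[seq_len(it_done)], as.data.frame))
  net <- linear_network(W, V, if (error_cov_mode == "scalar_precision")
    gamma else 1, error_cov_mode, sigma_eps)
  attr(net, "trajectory") <- traj
  net
}

#' Amari index of a transfer matrix
#'
#' Permutation- and scale-invariant separation score of the square transfer
#' matrix `A = W theta`: zero if and only if `A` is a scaled permutation (the
#' outputs recover the sources up to order, sign and scale), and 1 at maximal
#' mixing.  Normalised to `[0, 1]` by `N - 1`.
#'
#' @param transfer Square numeric matrix with no all-zero row or column.
#' @return The index in `[0, 1]`.
#' @export
amari_index <- function(transfer) {
  a <- abs(as.matrix(transfer))
  n <- nrow(a)
  if (ncol(a) != n) stop_invalid("transfer matrix must be square")
  if (any(apply(a, 1L, max) == 0) || any(apply(a, 2L, max) == 0))
    stop_invalid("transfer matrix has an all-zero row or column")
  rows <- sum(rowSums(a) / apply(a, 1L, max) - 1)
  cols <- sum(colSums(a) / apply(a, 2L, max) - 1)
  ((rows + cols) / (2 * n)) / (n - 1)
}

#' Write a fit trajectory as a delimited table
#'
#' @param network A network returned by [fit_fep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(network, path) {
  traj <- attr(network, "trajectory")
  if (is.null(traj)) stop_invalid("network carries no trajectory")
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
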
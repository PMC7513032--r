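# Shared fixture builders.  Everything is generated in code at test time.

default_grid <- function() coarse_graining(0.1, -6, 6)

# Tiny deterministic system used by plumbing tests.
tiny_system <- function(seed = 1L, M = 4L, N = 2L, noise_scale = 0.2,
                        n = 2000L, family = "laplace") {
  process <- make_random_process(M, N, noise_scale, seed, family)
  data <- simulate(process, nsim = n, seed = seed + 1L)
  list(process = process, data = data)
}

# Data whose empirical second-moment matrix is exactly the given diagonal.
exact_diag_data <- function(n, variances, seed = 1L) {
  set.seed(seed)
  d <- length(variances)
  x <- matrix(rnorm(n * d), n, d)
  x <- x %*% backsolve(chol(crossprod(x) / n), diag(d))
  sweep(x, 2L, sqrt(variances), "*")
}

expect_report_identities <- function(rep, tol = 1e-12) {
  expect_equal(rep$I_x_phi, rep$H_x - rep$H_x_given_phi, tolerance = tol)
  expect_equal(rep$X_util, rep$H_x - rep$L_X - rep$L_A, tolerance = tol)
  expect_equal(rep$F_bar, rep$I_x_phi - rep$X_util, tolerance = tol)
}
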
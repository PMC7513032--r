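test_that("recognition is the linear map u = W x", {
  net <- linear_network(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                        matrix(0, 4, 2))
  expect_equal(as.matrix(recognize(net, matrix(c(3, -1, 7, 2), 1))),
               matrix(c(3, -1), 1), ignore_attr = TRUE)
  net0 <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2))
  expect_true(all(as.matrix(recognize(net0, matrix(rnorm(40), 10))) == 0))
  net2 <- linear_network(rbind(c(1, 1), c(1, -1)), matrix(0, 2, 2))
  expect_equal(as.matrix(recognize(net2, matrix(c(2, 1), 1))),
               matrix(c(3, 1), 1), ignore_attr = TRUE)
  expect_error(recognize(net2, matrix(0, 1, 3)), "width")
})

test_that("recognition and reconstruction are linear and shape-checked", {
  set.seed(4)
  W <- matrix(rnorm(8), 2, 4); V <- matrix(rnorm(8), 4, 2)
  net <- linear_network(W, V)
  x <- matrix(rnorm(80), 20, 4)
  u <- recognize(net, x)
  expect_equal(as.matrix(recognize(net, 2.5 * x)), 2.5 * as.matrix(u),
               tolerance = 1e-12)
  e <- reconstruction_error(x, u, net)
  e2 <- reconstruction_error(2.5 * x, recognize(net, 2.5 * x), net)
  expect_equal(as.matrix(e2), 2.5 * as.matrix(e), tolerance = 1e-12)
  expect_error(reconstruction_error(x, as.matrix(u)[1:5, ], net), "rows")
})

test_that("reconstruction errors behave as the projection residual", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4)
  # V = 0 leaves the inputs untouched
  net0 <- linear_network(matrix(rnorm(8), 2, 4), matrix(0, 4, 2))
  u0 <- recognize(net0, x)
  expect_equal(as.matrix(reconstruction_error(x, u0, net0)), x,
               ignore_attr = TRUE)
  # orthonormal W with V = W': errors live in the null space of W
  W <- qr.Q(qr(matrix(rnorm(8), 4, 2)))[, 1:2]
  W <- t(W)
  net <- linear_network(W, t(W))
  u <- recognize(net, x)
  e <- as.matrix(reconstruction_error(x, u, net))
  expect_lt(max(abs(tcrossprod(e, W))), 1e-10)
  expect_equal(e, x %*% (diag(4) - crossprod(W)), tolerance = 1e-12)
  # exact reconstruction gives zero errors
  xr <- tcrossprod(as.matrix(u), t(W))  # x = V u exactly
  expect_lt(max(abs(as.matrix(
    reconstruction_error(xr, recognize(net, xr), net)))), 1e-10)
})

test_that("the model log likelihood carries its constants explicitly", {
  g1 <- coarse_graining(1, -6, 6)
  net <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2),
                        error_precision = 1)
  e0 <- matrix(0, 3, 4)
  ll <- model_log_likelihood(e0, net, g1)
  expect_equal(ll, rep(-2 * log(2 * pi), 3), tolerance = 1e-12)
  net2 <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2),
                         error_precision = 2)
  expect_equal(model_log_likelihood(e0, net2, g1) - ll,
               rep(2 * log(2), 3), tolerance = 1e-12)
  # row permutation invariance of the row-aligned map
  set.seed(6)
  e <- matrix(rnorm(40), 10, 4)
  perm <- sample(10)
  expect_equal(model_log_likelihood(e, net, g1)[perm],
               model_log_likelihood(e[perm, ], net, g1))
  # full covariance mode reduces to the scalar form when Sigma = I / gamma
  netf <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2),
                         error_cov_mode = "full_covariance",
                         error_covariance = diag(0.5, 4))
  net_g2 <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2),
                           error_precision = 2)
  expect_equal(model_log_likelihood(e, netf, g1),
               model_log_likelihood(e, net_g2, g1), tolerance = 1e-12)
  # definitional consistency with the reconstruction cost
  expect_equal(reconstruction_cost(e, net, g1),
               mean(-model_log_likelihood(e, net, g1)), tolerance = 1e-12)
})

test_that("prior log densities are correct and normalised", {
  expect_equal(prior_log_density(matrix(0, 1, 2), prior_spec("laplace", 1)),
               -log(2), tolerance = 1e-12)
  expect_equal(prior_log_density(matrix(0, 1, 1), prior_spec("gaussian", 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  for (fam in c("laplace", "gaussian")) {
    f1 <- function(u) exp(prior_log_density(matrix(u, ncol = 1),
                                            prior_spec(fam, 1)))
    expect_equal(integrate(f1, -10, 10)$value, 1, tolerance = 1e-4)
    f <- function(u) exp(prior_log_density(matrix(u, ncol = 1),
                                           prior_spec(fam, 2.5)))
    expect_equal(integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
    expect_equal(integrate(function(u) u^2 * f(u), -Inf, Inf)$value, 2.5,
                 tolerance = 1e-5)
  }
  expect_error(prior_log_density(matrix(0, 1, 2), prior_spec("flat")),
               "flat")
})

test_that("fine-tuning sets the error covariance to the empirical one", {
  sys <- tiny_system(seed = 3, n = 5000)
  net <- fit_pca(sys$data$inputs, 2)
  netf <- finetune_error_covariance(net, sys$data$inputs)
  expect_identical(netf$error_cov_mode, "full_covariance")
  e <- as.matrix(reconstruction_error(sys$data$inputs,
                                      recognize(net, sys$data$inputs), net))
  expect_equal(netf$error_covariance, crossprod(e) / nrow(e) + diag(1e-8, 4),
               tolerance = 1e-10)
})

test_that("network serialisation round-trips in both covariance modes", {
  set.seed(7)
  net <- linear_network(matrix(rnorm(8), 2, 4), matrix(rnorm(8), 4, 2),
                        error_precision = 3.25)
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  q <- read_network(path)
  expect_equal(q$recognition_matrix, net$recognition_matrix,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(q$generative_matrix, net$generative_matrix,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(q$error_precision, net$error_precision)
  sf <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  netf <- linear_network(net$recognition_matrix, net$generative_matrix,
                         error_cov_mode = "full_covariance",
                         error_covariance = sf)
  write_network(netf, path)
  qf <- read_network(path)
  expect_equal(qf$error_covariance, sf, tolerance = 1e-14,
               ignore_attr = TRUE)
})
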
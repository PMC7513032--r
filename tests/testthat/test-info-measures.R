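test_that("binned entropy handles degenerate, uniform and Gaussian cases", {
  g <- default_grid()
  # all mass in one bin: zero entropy, exactly
  expect_identical(binned_entropy(matrix(0.05, 1e4, 2), g), 0)
  # exactly uniform occupancy of K bins
  centers <- seq(-5.95, 5.95, by = 0.1)
  k <- 40L
  vals <- matrix(rep(centers[1:k], each = 25), ncol = 1)
  expect_equal(binned_entropy(vals, g), log(k), tolerance = 1e-12)
  # large-sample Gaussian: differential entropy plus the binning offset
  set.seed(1)
  g5 <- coarse_graining(0.1, -5, 5)
  h <- binned_entropy(matrix(rnorm(1e6), ncol = 1), g5)
  expect_lt(abs(h - (0.5 * log(2 * pi * exp(1)) - log(0.1))), 0.02)
  # guards
  expect_error(binned_entropy(matrix(0, 10, 5), g), "4 dimensions")
  expect_error(binned_entropy(matrix(numeric(0), 0, 1), g), "empty")
  # drop policy removes out-of-range rows; clip keeps them
  gd <- coarse_graining(0.1, -1, 1, clip_policy = "drop")
  v <- matrix(c(0, 0, 50), ncol = 1)
  expect_identical(binned_entropy(v, gd), 0)
  gc <- coarse_graining(0.1, -1, 1)
  expect_gt(binned_entropy(v, gc), 0)
})

test_that("adding independent jitter cannot decrease the binned output entropy", {
  set.seed(2)
  g <- default_grid()
  u <- matrix(rnorm(2e4, sd = 0.8), ncol = 2)
  h0 <- binned_entropy(u, g)
  for (sd_j in c(0.3, 1)) {
    hj <- binned_entropy(u + matrix(rnorm(length(u), sd = sd_j), ncol = 2), g)
    expect_gte(hj, h0 - 0.01)
  }
})

test_that("the quadrature marginal matches closed forms and normalises", {
  g <- default_grid()
  p <- make_random_process(2, 2, 0.2, seed = 42, source_family = "gaussian")
  d <- simulate(p, nsim = 500, seed = 7)
  x <- as.matrix(d$inputs)
  lq <- quadrature_log_marginal(p, NULL, x, g)
  sx <- tcrossprod(p$mixing_matrix) + p$noise_covariance
  ch <- chol(sx)
  w <- backsolve(ch, t(x), transpose = TRUE)
  lcf <- -0.5 * colSums(w^2) - sum(log(diag(ch))) - log(2 * pi) +
    2 * log(g$bin_width)
  expect_lt(max(abs(lq - lcf)), 1e-6)
  # identity projection: density integrates to 1 on a coarse M = 2 grid
  pl <- make_random_process(2, 2, 0.2, seed = 13)
  step <- 0.2
  pts <- as.matrix(expand.grid(seq(-6, 6, by = step), seq(-6, 6, by = step)))
  ld <- quadrature_log_marginal(pl, NULL, pts, g) - 2 * log(g$bin_width)
  expect_equal(sum(exp(ld)) * step^2, 1, tolerance = 1e-3)
  # Monte-Carlo average of negated values agrees with the binned entropy
  dl <- simulate(pl, nsim = 1e5, seed = 14)
  xl <- as.matrix(dl$inputs)
  hq <- mean(-quadrature_log_marginal(pl, NULL, xl[seq(1, 1e5, 10), ], g))
  hb <- binned_entropy(xl, g)
  expect_lt(abs(hq - hb), 0.05)
  expect_error(quadrature_log_marginal(
    make_random_process(4, 3, 0.2, seed = 1), NULL, matrix(0, 1, 4), g),
    "N <= 2")
})

test_that("mutual information follows the deterministic-map convention", {
  g <- default_grid()
  # u = x: everything the input carries is stored, H[x|phi] ~ 0
  p <- make_random_process(2, 2, 0.2, seed = 3)
  d <- simulate(p, nsim = 2e5, seed = 4)
  net <- linear_network(diag(2), diag(2))
  u <- recognize(net, d$inputs)
  mi <- mutual_information(p, net, d$inputs, u, g, "histogram",
                           n_eval = 20000)
  expect_equal(mi$I_x_phi, mi$H_x - mi$H_x_given_phi, tolerance = 1e-12)
  expect_lt(abs(mi$H_x_given_phi), 0.05)
  # constant outputs store nothing
  net0 <- linear_network(matrix(0, 2, 2), diag(2))
  mi0 <- mutual_information(p, net0, d$inputs, recognize(net0, d$inputs), g,
                            "histogram", n_eval = 2000)
  expect_identical(mi0$I_x_phi, 0)
  # all-Gaussian M = 2, N = 1: matches the closed-form Gaussian entropy of u
  pg <- make_random_process(2, 2, 0.3, seed = 5, source_family = "gaussian")
  dg <- simulate(pg, nsim = 1e5, seed = 6)
  W <- matrix(c(0.8, -0.4), 1, 2)
  netg <- linear_network(W, t(W))
  mig <- mutual_information(pg, netg, dg$inputs,
                            recognize(netg, dg$inputs), g, "histogram",
                            n_eval = 2000)
  sx <- tcrossprod(pg$mixing_matrix) + pg$noise_covariance
  su <- as.numeric(W %*% sx %*% t(W))
  I_cf <- 0.5 * log(2 * pi * exp(1) * su) - log(g$bin_width)
  expect_lt(abs(mig$I_x_phi - I_cf), 0.05)
})

test_that("the reconstruction cost has the right minimum and closed form", {
  g1 <- coarse_graining(1, -6, 6)
  net <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2), 1)
  expect_equal(reconstruction_cost(matrix(0, 10, 4), net, g1),
               2 * log(2 * pi), tolerance = 1e-12)
  # gamma* = M / <eps'eps> minimises L_X over gamma for fixed errors
  set.seed(8)
  e <- matrix(rnorm(400, sd = 0.7), 100, 4)
  lx_of_gamma <- function(gm) reconstruction_cost(
    e, linear_network(matrix(0, 2, 4), matrix(0, 4, 2), gm), g1)
  opt <- optimize(lx_of_gamma, c(1e-3, 100))
  expect_equal(opt$minimum, 4 / mean(rowSums(e^2)), tolerance = 1e-3)
  # the least-squares decoder beats V = 0 on the same data
  sys <- tiny_system(seed = 9, n = 5000)
  x <- as.matrix(sys$data$inputs)
  W <- fit_pca(x, 2)$recognition_matrix
  u <- x %*% t(W)
  V_ls <- t(solve(crossprod(u), crossprod(u, x)))
  net0 <- linear_network(W, matrix(0, 4, 2), 1)
  netls <- linear_network(W, V_ls, 1)
  g <- default_grid()
  lx0 <- reconstruction_cost(reconstruction_error(x, u, net0), net0, g)
  lxls <- reconstruction_cost(reconstruction_error(x, u, netls), netls, g)
  expect_lt(lxls, lx0)
})

test_that("the prior divergence is a calibrated, non-negative KL estimate", {
  g <- default_grid()
  p1 <- linear_generative_process(matrix(1), "laplace", matrix(0.01))
  net1 <- linear_network(matrix(1), matrix(1))
  # samples from the prior: divergence ~ 0 (1-D, where the plug-in bias
  # K/2n of the binned KL is negligible at n = 1e5)
  dl <- simulate(make_random_process(1, 1, 0.2, seed = 2), nsim = 1e5,
                 seed = 3)
  kl0 <- prior_divergence(p1, net1, dl$sources, prior_spec("laplace", 1), g,
                          "histogram")
  expect_lt(kl0, 0.02)
  expect_gte(kl0, 0)
  # standard normal vs unit-variance Laplace: 1-D quadrature oracle
  f <- function(u) dnorm(u) *
    (dnorm(u, log = TRUE) - (-0.5 * log(2) - sqrt(2) * abs(u)))
  kl_oracle <- integrate(f, -Inf, Inf)$value       # ~ 0.0560
  set.seed(4)
  klh <- prior_divergence(p1, net1, matrix(rnorm(1e6), ncol = 1),
                          prior_spec("laplace", 1), g, "histogram")
  expect_lt(abs(klh - kl_oracle), 0.005)
  # non-negativity under mismatch, both backends
  pg <- make_random_process(2, 1, 0.3, seed = 6, source_family = "gaussian")
  dg <- simulate(pg, nsim = 2e4, seed = 7)
  W <- matrix(c(2, 1), 1, 2)
  netg <- linear_network(W, t(W))
  u <- recognize(netg, dg$inputs)
  for (bk in c("histogram", "quadrature")) {
    kl <- prior_divergence(pg, netg, u, prior_spec("gaussian", 1), g, bk,
                           n_eval = 2000)
    expect_gte(as.numeric(kl), 0)
  }
  expect_error(prior_divergence(p1, net1, dl$sources, prior_spec("flat"), g),
               "flat")
})

test_that("report assembly enforces the information-accounting identities", {
  set.seed(10)
  for (i in 1:20) {
    H_x <- runif(1, 5, 12); H_u <- runif(1, 0, H_x)
    L_X <- runif(1, 0, 10); L_A <- runif(1, 0, 2)
    rep <- assemble_report(H_x, H_u, H_x - H_u, L_X, L_A, 1000L)
    expect_report_identities(rep)
    expect_equal(rep$F_approx, L_X + L_A, tolerance = 1e-12)
  }
  rep0 <- assemble_report(7, 3, 4, 0, 0, 100L)
  expect_equal(rep0$X_util, rep0$H_x, tolerance = 1e-12)
  expect_error(assemble_report(7, 3, 5, 0, 0, 100L), "inconsistent")
})

test_that("Gaussian closed forms: matched model reaches zero, mismatch stays above the surprise", {
  g <- default_grid()
  p <- make_random_process(2, 2, 0.2, seed = 42, source_family = "gaussian")
  net <- matched_network(p)
  cf <- gaussian_closed_form(p, net, g)
  expect_lt(abs(cf$S_bar), 1e-12)
  expect_lt(abs(cf$F_bar), 1e-12)
  # mismatched networks: F_bar >= S_bar >= 0 always
  set.seed(11)
  for (i in 1:10) {
    netm <- linear_network(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2),
                           error_precision = runif(1, 0.5, 20))
    cfm <- gaussian_closed_form(p, netm, g)
    expect_gte(cfm$S_bar, 0)
    expect_gte(cfm$F_bar, cfm$S_bar)
  }
  expect_error(gaussian_closed_form(make_random_process(2, 2, 0.2, seed = 1),
                                    net, g), "Gaussian")
})

test_that("the infomax objective prefers orthonormal rows and the principal axis", {
  set.seed(12)
  x <- matrix(rnorm(4000), 1000, 4) %*% diag(c(2, 1.5, 1, 0.5))
  W <- matrix(rnorm(8), 2, 4)
  Worth <- qr.Q(qr(t(W)))[, 1:2]
  Worth <- t(Worth)
  first_term <- function(W) {
    A <- diag(4) - crossprod(W) + diag(1e-3, 4)
    -as.numeric(determinant(A, logarithm = TRUE)$modulus)
  }
  expect_gt(first_term(Worth), first_term(W))
  # W = 0: the objective reduces to -M log(1 + eta)
  net0 <- linear_network(matrix(0, 2, 4), matrix(0, 4, 2))
  expect_equal(infomax_objective(net0, matrix(0, 10, 2), eta = 1e-3),
               -4 * log(1 + 1e-3), tolerance = 1e-12)
  # brute-force rotation search recovers the principal axis (M = 2, N = 1)
  x2 <- exact_diag_data(2000, c(3, 1), seed = 13)
  angles <- seq(0, pi, length.out = 721)
  vals <- vapply(angles, function(a) {
    W1 <- matrix(c(cos(a), sin(a)), 1, 2)
    infomax_objective(linear_network(W1, t(W1)), x2 %*% t(W1))
  }, 0)
  best <- angles[which.max(vals)]
  pc1 <- fit_pca(x2, 1)$recognition_matrix
  ang <- principal_angles(matrix(c(cos(best), sin(best)), 1, 2), pc1)
  expect_lt(max(ang), 0.01)
})

test_that("nats convert to bits at 1.4427 bits per nat", {
  expect_equal(round(nats_to_bits(1), 4), 1.4427)
  expect_identical(nats_to_bits(0), 0)
  expect_equal(round(nats_to_bits(2), 4), 2.8854)
})
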
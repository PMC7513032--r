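#' Replication experiment configuration
#'
#' Settings for the three-condition comparison (random, infomax/PCA and
#' free-energy-optimised networks) on freshly drawn linear mixtures.  The
#' default scale — 1e5 samples, 20 repeats — runs in minutes on one CPU;
#' the original study scale (1e8 samples, 100 repeats) is reachable by
#' configuration but is only executed when `run_replication(force = TRUE)`.
#'
#' @param M,N Input and source/output dimensions (defaults 4 and 2).
#' @param n_samples Samples per repeat (`>= 1000`).
#' @param repeats Number of repeats (`>= 1`).
#' @param noise_scale Noise scale passed to [make_random_process()].
#' @param conditions Non-empty subset of `c("random", "pca", "fep")`.
#' @param source_family `"laplace"` (default) or `"gaussian"`.
#' @param grid A [coarse_graining()].
#' @param backend `"histogram"` or `"quadrature"`.
#' @param master_seed Integer master seed; each repeat derives child seeds
#'   from it by counter, so adding repeats never shifts earlier draws.
#' @param n_eval Subsample size for quadrature Monte-Carlo averages.
#' @param fit A [fit_config()] for the FEP condition.
#' @param output_path Optional CSV path for the result table (a `.meta.txt`
#'   sidecar records the configuration).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(M = 4L, N = 2L, n_samples = 1e5L,
                              repeats = 20L, noise_scale = 0.2,
                              conditions = c("random", "pca", "fep"),
                              source_family = c("laplace", "gaussian"),
                              grid = coarse_graining(),
                              backend = c("histogram", "quadrature"),
                              master_seed = 1L, n_eval = 4000L,
                              fit = fit_config(), output_path = NULL) {
  source_family <- match.arg(source_family)
  backend <- match.arg(backend)
  conditions <- match.arg(conditions, c("random", "pca", "fep"),
                          several.ok = TRUE)
  check_scalar_number(repeats, "repeats", positive = TRUE, integer = TRUE)
  check_scalar_number(n_samples, "n_samples", positive = TRUE, integer = TRUE)
  if (n_samples < 1e3) stop_invalid("need n_samples >= 1000")
  check_scalar_number(master_seed, "master_seed", integer = TRUE)
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_samples = n_samples, repeats = as.integer(repeats),
                 noise_scale = noise_scale, conditions = conditions,
                 source_family = source_family, grid = grid,
                 backend = backend, master_seed = as.integer(master_seed),
                 n_eval = n_eval, fit = fit, output_path = output_path),
            class = "experiment_config")
}

#' Evaluate a network on simulated data
#'
#' Runs the full measurement pipeline — recognition, reconstruction errors,
#' entropies, reconstruction cost and prior divergence — and assembles an
#' [assemble_report()].
#'
#' @param process The [linear_generative_process()] that generated the data.
#' @param network A [linear_network()].
#' @param inputs Inputs batch.
#' @param grid A [coarse_graining()].
#' @param backend `"histogram"` or `"quadrature"`.
#' @param prior Output prior for the divergence term (default: unit-variance
#'   prior of the process's source family).
#' @param n_eval Quadrature Monte-Carlo subsample size.
#' @param H_x Optional precomputed `H[x]` (it depends only on the process and
#'   data, so it can be shared across networks).
#' @return An `info_report`.
#' @export
evaluate_network <- function(process, network, inputs, grid = coarse_graining(),
                             backend = c("histogram", "quadrature"),
                             prior = NULL, n_eval = 4000L, H_x = NULL) {
  backend <- match.arg(backend)
  if (is.null(prior)) prior <- prior_spec(process$source_family, 1)
  outputs <- recognize(network, inputs)
  errors <- reconstruction_error(inputs, outputs, network)
  mi <- mutual_information(process, network, inputs, outputs, grid, backend,
                           n_eval = n_eval, H_x = H_x)
  L_X <- reconstruction_cost(errors, network, grid)
  L_A <- prior_divergence(process, network, outputs, prior, grid, backend,
                          n_eval = n_eval)
  assemble_report(mi$H_x, mi$I_x_phi, mi$H_x_given_phi, L_X, L_A,
                  nrow(batch_values(inputs)), backend)
}

# Build the condition's network on the given data.
condition_network <- function(condition, inputs, config, seeds) {
  x <- batch_values(inputs)
  M <- ncol(x); N <- config$N
  switch(condition,
    random = {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seeds[3L])
      W <- matrix(stats::rnorm(N * M), N, M)
      W <- W / sqrt(rowSums(W^2))
      resid <- x - x %*% crossprod(W)
      linear_network(W, t(W), optimal_gamma(M, mean(rowSums(resid^2))))
    },
    pca = fit_pca(inputs, N, "closed_form"),
    fep = {
      fc <- config$fit
      fc$seed <- seeds[4L]
      fit_fep(inputs, N, prior_spec(config$source_family, 1), fc)
    },
    stop_invalid(sprintf("unknown condition '%s'", condition)))
}

#' Run one condition of the replication experiment
#'
#' Builds the condition's network on the shared data (`random`: unit-row
#' random `W` with `V = W'`; `pca`: [fit_pca()] closed form; `fep`:
#' [fit_fep()]), evaluates it into an information report, and appends the
#' Amari index of the transfer matrix `W theta`.
#'
#' @param process The generative process behind `data`.
#' @param data List with `sources` and `inputs` batches (from
#'   [simulate.linear_generative_process()]).
#' @param condition `"random"`, `"pca"` or `"fep"`.
#' @param config An [experiment_config()].
#' @param seeds Integer vector of per-repeat child seeds.
#' @param H_x Optional shared `H[x]`.
#' @return One-row data frame of the result table.
#' @export
run_condition <- function(process, data, condition, config,
                          seeds = derive_seeds(config$master_seed, 0L),
                          H_x = NULL) {
  network <- condition_network(condition, data$inputs, config, seeds)
  rep_row <- evaluate_network(process, network, data$inputs, config$grid,
                              config$backend, prior_spec(config$source_family,
                                                         1),
                              config$n_eval, H_x = H_x)
  df <- as.data.frame(rep_row)
  transfer <- network$recognition_matrix %*% process$mixing_matrix
  df$amari_index <- if (nrow(transfer) == ncol(transfer))
    amari_index(transfer) else NA_real_
  cbind(data.frame(condition = condition), df)
}

#' Run the replication experiment
#'
#' For each repeat: derive child seeds from the master seed, draw a fresh
#' random process (`theta`, `Sigma_z`), simulate one dataset, and evaluate
#' every requested condition on that same dataset (sharing the data — and the
#' input entropy `H[x]` — across conditions pairs them, reducing the variance
#' of between-condition comparisons).
#'
#' @param config An [experiment_config()].
#' @param force Set `TRUE` to actually execute configurations beyond the
#'   default desk scale (more than 1e6 samples or 50 repeats); otherwise such
#'   configurations return an empty table that echoes the configuration.
#' @return A `result_table` data frame: one row per condition and repeat with
#'   every information measure plus the Amari index, the configuration in
#'   attribute `"config"`.  Written to `config$output_path` (with a
#'   `.meta.txt` sidecar) when set.
#' @export
run_replication <- function(config, force = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  big <- config$n_samples > 1e6 || config$repeats > 50
  if (big && !force) {
    message(sprintf(
      "configuration (n_samples = %g, repeats = %d) exceeds desk scale; ",
      config$n_samples, config$repeats),
      "returning the configuration echo only (use force = TRUE to run)")
    out <- empty_result_table()
    attr(out, "config") <- config
    class(out) <- c("result_table", class(out))
    return(out)
  }
  if (!is.null(config$output_path)) {        # fail before computing
    con <- try(file(config$output_path, "w"), silent = TRUE)
    if (inherits(con, "try-error"))
      stop_invalid("cannot write to output path ", config$output_path)
    close(con)
  }
  rows <- vector("list", config$repeats * length(config$conditions))
  k <- 0L
  for (r in seq_len(config$repeats)) {
    seeds <- derive_seeds(config$master_seed, r)
    process <- make_random_process(config$M, config$N, config$noise_scale,
                                   seeds[1L], config$source_family)
    data <- stats::simulate(process, nsim = config$n_samples,
                            seed = seeds[2L])
    idx <- eval_subsample(config$n_samples, config$n_eval)
    H_x <- mean(-quadrature_log_marginal(
      process, NULL, batch_values(data$inputs)[idx, , drop = FALSE],
      config$grid))
    for (cond in config$conditions) {
      k <- k + 1L
      row <- run_condition(process, data, cond, config, seeds, H_x = H_x)
      row <- cbind(data.frame(repeat_index = r, seed = seeds[1L]), row)
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("condition", setdiff(names(out), "condition"))]
  attr(out, "config") <- config
  class(out) <- c("result_table", class(out))
  if (!is.null(config$output_path)) write_result_table(out,
                                                       config$output_path)
  out
}

empty_result_table <- function() {
  data.frame(condition = character(), repeat_index = integer(),
             seed = integer(), H_x = numeric(), H_x_given_phi = numeric(),
             I_x_phi = numeric(), L_X = numeric(), L_A = numeric(),
             X_util = numeric(), F_bar = numeric(), F_approx = numeric(),
             n_samples = integer(), backend = character(),
             amari_index = numeric())
}

#' Write / read a result table
#'
#' The table itself goes to a comma-delimited file with headers; the
#' configuration echo goes to a `.meta.txt` key/value sidecar.
#'
#' @param table A `result_table`.
#' @param path CSV path.
#' @return `write_result_table()` returns `path` invisibly;
#'   `read_result_table()` the table (re-validating the accounting identities
#'   of every row on load).
#' @export
write_result_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    meta <- c(sprintf("package_version=%s",
                      as.character(utils::packageVersion("utilinfo"))),
              sprintf("M=%d", cfg$M), sprintf("N=%d", cfg$N),
              sprintf("n_samples=%g", cfg$n_samples),
              sprintf("repeats=%d", cfg$repeats),
              sprintf("noise_scale=%g", cfg$noise_scale),
              sprintf("conditions=%s", paste(cfg$conditions, collapse = ",")),
              sprintf("source_family=%s", cfg$source_family),
              sprintf("backend=%s", cfg$backend),
              sprintf("master_seed=%d", cfg$master_seed),
              sprintf("n_eval=%g", cfg$n_eval),
              sprintf("bin_width=%g", cfg$grid$bin_width),
              sprintf("range=[%g,%g]", cfg$grid$lower, cfg$grid$upper))
    writeLines(meta, paste0(path, ".meta.txt"))
  }
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  tol <- 1e-9
  with(out, {
    if (any(abs(I_x_phi - (H_x - H_x_given_phi)) > tol) ||
        any(abs(X_util - (H_x - L_X - L_A)) > tol) ||
        any(abs(F_bar - (I_x_phi - X_util)) > tol))
      stop_invalid("result table violates the information-accounting ",
                   "identities")
  })
  class(out) <- c("result_table", class(out))
  out
}

#' Summarise a replication result table
#'
#' Per-condition medians of every measure, plus the ordering flags the theory
#' predicts: the free-energy-optimised networks should reach lower median
#' `F_bar` than PCA, PCA lower than random; PCA should minimise the median
#' conditional entropy `H[x|phi]`; and FEP should separate sources better
#' (lower median Amari index) than PCA.  Flags involving a missing condition
#' are `NA`.
#'
#' @param table A `result_table` with at least one condition.
#' @return A list with `medians` (data frame) and `flags` (named logical).
#' @export
summarize_results <- function(table) {
  tab <- as.data.frame(table)
  if (nrow(tab) == 0L) stop_invalid("empty result table")
  measures <- c("H_x", "H_x_given_phi", "I_x_phi", "L_X", "L_A", "X_util",
                "F_bar", "F_approx", "amari_index")
  meds <- do.call(rbind, lapply(split(tab, tab$condition), function(d)
    cbind(data.frame(condition = d$condition[1L]),
          as.data.frame(lapply(d[measures], stats::median)))))
  rownames(meds) <- NULL
  med_of <- function(cond, m) {
    i <- match(cond, meds$condition)
    if (is.na(i)) NA_real_ else meds[[m]][i]
  }
  flags <- c(
    F_fep_lt_pca = med_of("fep", "F_bar") < med_of("pca", "F_bar"),
    F_pca_lt_random = med_of("pca", "F_bar") < med_of("random", "F_bar"),
    Hx_given_phi_pca_le_fep =
      med_of("pca", "H_x_given_phi") <= med_of("fep", "H_x_given_phi"),
    amari_fep_lt_pca =
      med_of("fep", "amari_index") < med_of("pca", "amari_index"))
  list(medians = meds, flags = flags)
}

#' Scatter plot of a result table
#'
#' Conditional entropy against free-energy expectation, one point per repeat,
#' coloured by condition (black: random, blue: PCA/infomax, red: FEP).
#'
#' @param x A `result_table`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.result_table <- function(x, ...) {
  tab <- as.data.frame(x)
  cols <- c(random = "black", pca = "blue", fep = "red")
  graphics::plot(tab$H_x_given_phi, tab$F_bar,
                 col = cols[tab$condition], pch = 19,
                 xlab = "H[x|phi] (nats)", ylab = "F_bar (nats)", ...)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
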
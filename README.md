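# utilinfo

Information accounting for linear blind source separation: how much
information does a neural network *store* about its sensory inputs, and how
much of it can it actually *use* for inference?

## The problem

A linear world draws N independent, zero-mean, unit-variance hidden sources
`s` (Laplace or Gaussian) and mixes them into M noisy sensory channels,

```
x = θ s + z,   z ~ N(0, Σz).
```

A linear network encodes the inputs with a recognition model `u = W x` and
explains them with a generative model `x = V u + ε`, a Gaussian likelihood
`p*(x|u) = N(x; Vu, Σε(γ))` and a factorised output prior `p₀(u)`.

Two classical principles make different demands on `W`.  The **infomax
principle** maximises the stored information `I[x;φ]`; with the tied-weights
constraint `V = Wᵀ` its solution is PCA.  The **free-energy principle (FEP)**
minimises the free-energy expectation `F̄`, which decomposes into a
reconstruction cost `L_X` (the PCA term) plus the divergence of the outputs
from their prior `L_A` (Amari's ICA cost) — its solution performs blind
source separation.  The bridge between them is the **utilizable
information**

```
X[x;φ] = H[x] − L_X − L_A,          F̄ = I[x;φ] − X[x;φ],
```

so the free energy is exactly the gap between stored and utilizable
information.  All quantities are *coarse-grained* at resolution Δ (default
0.1 on [−6, 6]) and reported in nats; the accounting identities above hold to
machine precision in every report the package produces.

The package provides:

* `make_random_process()` / `simulate()` — the synthetic world, with exact
  seeded reproducibility;
* histogram and quadrature estimators of `H[x]`, `H[x|φ]`, `I[x;φ]`, `L_X`,
  `L_A`, `X[x;φ]`, `F̄` (`binned_entropy()`, `quadrature_log_marginal()`,
  `evaluate_network()`), plus all-Gaussian closed forms
  (`gaussian_closed_form()`, `matched_network()`);
* learning rules: `fit_pca()` (eigendecomposition or Oja's subspace rule) and
  `fit_fep()` (alternating exact decoder/precision updates with
  natural-gradient ICA encoder steps), scored by `amari_index()`;
* `run_replication()` — the three-condition experiment (random / PCA / FEP
  networks on shared data) with `summarize_results()` and a scatter plot of
  `(H[x|φ], F̄)`;
* a command-line interface (`utilinfo_cli()`, installed script
  `inst/cli/utilinfo`) with `simulate`, `fit`, `evaluate`, `replicate` and
  `summarize` subcommands.

## Worked example

```r
library(utilinfo)
grid <- coarse_graining(0.1, -6, 6)

process <- make_random_process(M = 4, N = 2, noise_scale = 0.2, seed = 1)
data <- simulate(process, nsim = 1e5, seed = 2)

pca <- fit_pca(data$inputs, N = 2)
fep <- fit_fep(data$inputs, N = 2, prior_spec("laplace", 1))

evaluate_network(process, pca, data$inputs, grid)
#> <info_report> (histogram backend, n = 100000) [nats]
#>   H[x] = 11.2875   H[x|phi] = 3.9956   I[x;phi] = 7.2919
#>   L_X  = 6.5483   L_A      = 0.1609
#>   X[x;phi] = 4.5783   F_bar = 2.7136   (F_approx = 6.7092)
evaluate_network(process, fep, data$inputs, grid)
#> <info_report> (histogram backend, n = 100000) [nats]
#>   H[x] = 11.2875   H[x|phi] = 4.0303   I[x;phi] = 7.2571
#>   L_X  = 6.5483   L_A      = 0.0438
#>   X[x;phi] = 4.6953   F_bar = 2.5618   (F_approx = 6.5921)

amari_index(pca$recognition_matrix %*% process$mixing_matrix)
#> [1] 0.8883044
amari_index(fep$recognition_matrix %*% process$mixing_matrix)
#> [1] 0.004352657
```

Reading the numbers: both networks capture the same two-dimensional subspace
(equal `L_X`, similar stored information `I[x;φ]`), but the FEP network has
rotated its outputs onto the independent sources — its output distribution
nearly matches the Laplace prior (`L_A` 0.04 vs 0.16 nats), its free energy
is lower, its utilizable information higher, and its Amari index of 0.004
says the transfer matrix `Wθ` is a scaled permutation: the sources are
recovered.  PCA, at Amari index 0.89, stores as much information but in a
mixed, unusable basis.

The full three-condition replication (20 repeats, 10⁵ samples each):

```r
tab <- run_replication(experiment_config(master_seed = 1))
summarize_results(tab)
```

which yields median `F̄`: FEP 2.47 < PCA 2.60 < random 8.39 nats, with all 20
FEP runs below Amari index 0.1.

## Documentation

The methods vignette (`vignettes/utilizable-information.Rmd`) documents the
model and its assumptions, the two estimator backends and their error
budgets, the two free-energy conventions, the optimiser design, and known
limitations of the synthetic-world generator.
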
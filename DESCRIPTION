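Package: utilinfo
Title: Utilizable Information and Free-Energy Accounting for Linear Blind
    Source Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates linear blind-source-separation systems (independent
    Laplace or Gaussian sources mixed into noisy sensory inputs) and measures,
    in coarse-grained nats, the information a linear neural network stores
    about its inputs versus the information it can actually use for inference.
    Provides histogram and quadrature estimators of entropy, mutual
    information, reconstruction cost, and the divergence between output and
    prior distributions; closed-form Gaussian free-energy expectations; the
    utilizable-information decomposition tying the free-energy principle to
    the infomax principle; PCA (Oja subspace / closed-form) and
    free-energy-minimising (natural-gradient ICA) learning rules; an Amari
    index for separation quality; and a replication experiment comparing
    random, infomax-optimal, and free-energy-optimal networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
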
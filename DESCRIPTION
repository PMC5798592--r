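Package: beliefprop
Title: Belief Propagation Engines for Active Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating active inference as neuronal message passing on
    factor graphs. Provides discrete (Markov decision process) marginal belief
    propagation with expected-free-energy policy selection, continuous generalized
    filtering (predictive coding) with active sampling, and the Gaussian link
    factor that couples the two regimes through Bayesian model averaging and post
    hoc (reduced) Bayesian model comparison. Includes brute-force oracles for
    testing, a deep-temporal (two-level) scheduler, and a complete pictographic
    reading simulation with a synthetic glyph world, saccadic visual sampling and
    simulated electrophysiology (firing-rate rasters and band-passed local field
    potentials).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
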
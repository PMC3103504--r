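Package: sarcodyn
Title: Dynamical Modeling of Granulomatous Inflammation in Sarcoidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the Th1-type immune
    response underlying granuloma formation in sarcoidosis. Implements a
    minimal bistable switch for effector T cell (Th1) activation and a
    six-variable network of effector T cells, regulatory T cells,
    macrophages and the cytokines IL-2, IFN-gamma and TNF-alpha. Provides
    square-pulse perturbation protocols (antigen challenge and cytokine
    inhibitor therapy), steady-state and hysteresis analysis of the
    bistable switch, threshold finding over pulse amplitudes, durations
    and parameters, coarse-grained classification of long-term states
    onto the eight low/high immune phenotypes, and in-silico monotherapy
    and combination-therapy titration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
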
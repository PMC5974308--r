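Package: pathdyn
Title: Learning Metabolic Pathway Dynamics from Time-Series Multiomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts metabolic pathway dynamics from time-series proteomics
    and metabolomics data by learning the metabolite vector field dm/dt =
    f(m, p) directly from state-derivative training pairs. Provides
    Savitzky-Golay smoothing and data augmentation of sparse fermentation
    time series, per-metabolite regressor selection by cross-validated RMSE,
    trajectory prediction by adaptive Runge-Kutta integration of the learned
    field, a ground-truth Michaelis-Menten kinetic model of the
    limonene-producing mevalonate pathway with a leaky-Hill virtual strain
    generator, strain production-ranking and training-set-scaling
    experiments, a differential-evolution kinetic-model fitting baseline,
    and partial-least-squares analysis of final-time proteomics against
    product titer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    caret,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mixOmics,
    optparse,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
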
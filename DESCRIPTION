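Package: petrdp
Title: Stochastic Variance-Reduced Reconstruction for Penalized PET with the
    Relative Difference Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for penalized maximum a posteriori reconstruction of
    Poisson (PET-like) projection data with the relative difference prior.
    Provides a desk-scale tomographic forward model, the separable
    Kullback-Leibler data fidelity and relative difference prior with
    analytic gradients and diagonal Hessians, MLEM and harmonic-mean
    diagonal preconditioners, stochastic gradient estimators (SGD, SAGA,
    SVRG), subset ordering strategies including Herman-Meyer and cofactor
    orders, constant/vanishing/Barzilai-Borwein stepsize rules, an OSEM
    initializer, a bound-constrained quasi-Newton reference solver, and a
    simulation benchmark harness with phantom generation, Poisson
    acquisition simulation and NRMSE convergence reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
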
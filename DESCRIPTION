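Package: cetadens
Title: Hierarchical Bayesian Inference of Cetacean Population Density
    from Absolute Dynamic Topography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits hierarchical Bayesian line-transect distance-sampling
    models that link cetacean population density to the absolute dynamic
    topography (ADT) of the ocean surface.  The observational process
    couples a half-normal detection function, whose effective strip
    half-width depends log-linearly on Beaufort sea state and group size,
    with Poisson group counts in 1/3-degree grid cells; the ecological
    process models density as a log-polynomial function of rescaled ADT.
    Includes a synthetic survey generator (smooth ADT fields, zig-zag
    transects, half-normal detections, Poisson or log-normal group
    sizes), survey gridding utilities, an adaptive Metropolis-within-
    Gibbs sampler, convergence diagnostics (Gelman-Rubin R-hat, batch-
    means Monte Carlo error), DIC model selection, posterior predictive
    Bayesian p-values, and prediction of density surfaces with credible
    bands stratified by ENSO state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
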
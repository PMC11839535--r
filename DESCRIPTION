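Package: fractamorph
Title: Brain Morpho-Structural Complexity and Behavior via Box-Counting
    Fractal Dimension, ROI Fractional Anisotropy and PLS Correlation
Version: 0.1.0
Authors@R:
    person("Fractamorph", "Developers", email = "fractamorph@example.org",
           role = c("aut", "cre"))
Description: Tools to relate brain morpho-structural measures to cognitive
    and balance outcomes. Estimates the fractal dimension of 3-D binary
    structures by box counting (general structure, boundary surface and
    topological skeleton features), computes ROI-mean fractional anisotropy
    from scalar maps and integer label atlases, derives a center-of-pressure
    path-length statistic from force-platform perturbation trials, and links
    an imaging feature block to a behavioral block with behavioral partial
    least squares correlation (SVD of the cross-block covariance) including
    permutation significance testing and bootstrap stability ratios. A
    synthetic-data module generates fractal phantoms of known dimension,
    rank-1 latent-variable cohorts, labeled volumes and perturbation traces
    so the full pipeline runs end-to-end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
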
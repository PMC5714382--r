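Package: mvpdR
Title: Multivariate Pattern Dependence for fMRI Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-validated multivariate pattern dependence (MVPD) between
    brain regions. Each region's BOLD response is modeled as a trajectory in a
    PCA-derived representational space estimated on training runs; statistical
    dependence between two regions is quantified by how well one region's
    trajectory linearly predicts the other's in held-out runs. Includes
    matrix-level preprocessing (discrete-cosine high-pass filtering, CompCor
    nuisance components, nuisance regression, censoring, univariate-signal
    removal), univariate functional-connectivity baselines, searchlight
    mapping over a gray-matter mask, per-dimension maps and map similarity,
    one-sample sign-flip permutation inference with max-statistic family-wise
    error control, a synthetic multi-run data generator with known ground
    truth, and NIfTI volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
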
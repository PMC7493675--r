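Package: lazone
Title: Regional Quantification of Leukoaraiosis by White Matter Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies leukoaraiosis (white matter hyperintensities on
    FLAIR MRI) as a percentage of regional white matter, by cortical depth
    (periventricular, deep, infracortical bands built with a spacing-aware
    Euclidean distance transform) and by anterior/posterior lobe partition,
    together with lacunae and stroke volumetrics and the accompanying
    statistical battery (log screening, group tests, mixed-design ANCOVA
    with partial eta squared, and covariate-adjusted partial correlations).
    Includes a synthetic brain-phantom generator with planted lesion loads
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
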
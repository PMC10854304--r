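Package: placentadr
Title: Combined Diffusion-Relaxation MRI Analysis of the Placenta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for combined diffusion-relaxation (T2*-ADC) placental
    MRI. Provides voxelwise joint T2*-ADC model fitting, data-driven
    decomposition of multi-echo multi-b-value signals into tissue-environment
    components with two-dimensional T2*-ADC spectra and voxelwise weight maps
    (spectra learned from a control cohort, or fixed and re-applied to new
    scans), synthetic placental phantoms and cohorts with known ground truth,
    and cohort-level statistics (covariate-adjusted group comparisons,
    gestational-age trends, and false-discovery-rate correction across
    components).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
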
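Package: bhcvr
Title: Breath-Hold Cerebrovascular Reactivity Mapping for Stroke fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative mapping of cerebrovascular reactivity (CVR) from
    breath-hold BOLD fMRI in stroke. Builds an end-tidal CO2 regressor from a
    raw capnograph trace (peak detection, breath-hold interpolation,
    scale-invariant convolution with a double-gamma haemodynamic response
    function), estimates voxelwise CVR in %BOLD per mmHg with three
    delay-aware estimators (globally delay-optimised GLM, voxelwise
    delay-optimised GLM, and regression on the contralesional-hemisphere mean
    signal), constructs lesion, peri-infarct, healthy and homologous-region
    masks by millimetre dilation and left/right reflection, and summarises
    CVR amplitude and haemodynamic delay over regions with an R-squared
    admission threshold. Includes a synthetic stroke phantom generator with
    known CVR, delay, drift and noise structure for end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
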
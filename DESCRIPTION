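Package: cropdiv
Title: Spatio-Temporal Crop Diversity Analysis for District Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-run change in crop species diversity
    from district-by-year-by-crop area and production panels. Harmonizes
    panels across administrative boundary changes, imputes gaps by temporal
    interpolation, and aggregates to state and country level. Computes the
    effective number of crop species (the exponential of Shannon entropy),
    a crop-count adjustment based on fitting a saturating exponential to
    subsampled diversity values, and multiplicative alpha/beta/gamma
    diversity partitions. Builds crop-to-crop area transition matrices
    between period means under a conservative within-district assumption,
    and relates change in diversity to agricultural intensification through
    an AIC-selected ladder of linear models on a relative-intensity index.
    Includes a synthetic panel generator that emulates cereal
    intensification and smallholder diversification dynamics so the whole
    pipeline is testable without external data compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
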
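Package: cropgap
Title: Cropping-System Yield Gap Analysis on an Annual Calendar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends yield-gap analysis from single crops to whole cropping
    systems. Given potential-yield response surfaces over sowing or
    transplanting dates (from crop-model output or a built-in stochastic
    surrogate), the package enumerates all feasible annual crop sequences on
    a circular 365-day calendar under turnaround and stability constraints,
    selects the alternative system with the highest stable energy yield,
    decomposes cropping-system yield gaps into crop-management and
    crop-arrangement components, and estimates the nitrogen, water and
    radiation capture required to realise potential yields. Ships the
    Bangladesh rice-maize case-study tables as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
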
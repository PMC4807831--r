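Package: washoutpet
Title: Biological Washout Analysis of Point-Source Dynamic PET Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure biological washout of positron-emitting
    radionuclides from dynamic PET acquisitions of a point-like source.
    Simulates seeded synthetic preclinical 11C studies (Gaussian point
    spread, Poisson counting noise, alive and dead conditions), extracts
    region-of-interest time-activity curves with decay correction, and
    decomposes the biological signal into tissular-diffusion and
    vascular-washout exponential components with per-animal fits and
    group summaries.
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
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
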
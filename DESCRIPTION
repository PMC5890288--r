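Package: phenomatch
Title: Camera-Satellite Vegetation Phenology Intercomparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving vegetation phenology transition dates from
    digital repeat photography ("phenocam") colour time series and comparing
    them with satellite land-surface phenology retrievals. Computes the green
    chromatic coordinate (Gcc) from image colour summaries with solar-elevation
    and brightness screening, aggregates it over moving windows, smooths the
    series with an AIC-selected cubic smoothing spline, rejects outliers,
    segments greenness-rising and greenness-falling phases with an in-package
    PELT changepoint detector, and extracts amplitude-threshold transition
    dates with spline-based 90% confidence intervals. Satellite support covers
    NDVI from red/NIR nadir reflectances, 3x3-pixel window envelopes, and
    IGBP landcover majority classification. Agreement between camera and
    satellite dates is quantified with bias statistics, Pearson correlation,
    errors-in-variables (Deming/orthogonal) regression with jackknife
    standard errors, and RMS perpendicular regression distances, stratified
    by vegetation-type representativeness ("apples to apples" versus
    "apples to oranges"). A coupled synthetic-scene generator with known
    ground-truth transition dates makes the whole pipeline testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
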
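Package: zooseis
Title: Zooplankton Mortality and Vertical Distribution Around Seismic
    Airgun Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for field studies of zooplankton responses
    to seismic airgun surveys. Computes broadband sound exposure level and
    peak-to-peak pressure from calibrated hydrophone recordings, vertical
    distribution indicators (center of mass, inertia, nautical area
    scattering coefficient) from gridded echosounder volume backscatter,
    live/dead classification of Neutral Red stained zooplankton images by
    color thresholding, and the associated mortality statistics (rank
    tests, binomial generalized linear models with treatment-by-time
    interaction, Monte Carlo power analysis). Includes synthetic data
    generators that emulate an airgun approach experiment end to end, so
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    EBImage,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
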
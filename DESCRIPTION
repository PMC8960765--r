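Package: laifusion
Title: Daily 3 m Leaf Area Index from Multi-Sensor Fusion and Rule-Based Downscaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid retrieval of daily, gap-free leaf area index (LAI) maps at
    3 m from a two-sensor surface-reflectance stream: an intermittent 9-band
    30 m sensor (Sentinel-2-like) and a daily 4-band 3 m sensor (harmonized
    CubeSat-like). Coarse-sensor LAI is estimated by an ensemble of random
    forests trained on canopy radiative-transfer forward simulations over
    vegetation indices; multi-date coarse LAI is corrected for crop growth
    between acquisitions with a vegetation-index change model, weighted and
    outlier-screened into a per-date 30 m reference; and a rule-based model
    tree trained at 30 m transfers the reference to 3 m daily maps. Includes
    a synthetic maize-campaign simulator with known truth, field-plot
    evaluation (RMSE, rRMSE, R-squared) and phenology-stage analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
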
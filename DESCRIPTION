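Package: echotrends
Title: Echo-Integration and Trend Analysis for Pelagic Acoustic Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing and long-term trend analysis of fisheries-acoustics
    survey data. Echo-integrates gridded volume-backscattering-strength (Sv)
    echograms into Nautical Area Scattering Coefficients (NASC) per elementary
    sampling distance unit, classifies backscatter into trophic echo classes by
    dB thresholding, labels records day/night from solar altitude and builds
    diel-vertical-migration profiles, computes biomass-weighted barycenters and
    their displacement, and provides climatology, anomaly and rank-based trend
    machinery for monthly environmental series. A synthetic-survey generator
    emulates migrating scattering layers and seasonal environmental series with
    known ground truth so every stage is testable without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
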
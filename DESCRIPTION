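Package: duckquant
Title: Growth Quantification and Salinity Dose-Response Analysis for
    Floating Aquatic Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based growth phenotyping of small floating aquatic
    plants (duckweed, Lemnaceae) cultured in barcoded tube racks.
    Segments plant material from top-view photographs by LAB
    green-magenta thresholding and reports per-tube surface area;
    measures floating-mat depth and decodes Code128 sample barcodes
    from side-view photographs with a threshold/rotation retry search;
    joins both views into per-sample growth curves; estimates relative
    growth rates by sliding-window log-linear fits with an adjusted
    R-squared gate; and quantifies salinity tolerance by fitting
    five-parameter log-logistic dose-response curves, solving for the
    EC50 relative to the 0 mM growth rate, and bootstrapping its
    standard deviation. A synthetic fixture generator renders
    ground-truthed tube images and trial-scale growth data so the
    whole pipeline is testable without an imaging rig.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
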
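Package: canopylai
Title: Rice Leaf Area Index Estimation from Spectral Indices and
    Multi-Scale Image Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating rice leaf area index (LAI) from
    high-resolution canopy imagery. Simulates field scenes with known
    per-plot LAI (RGB-like digital-number imagery and twelve-band
    multispectral reflectance imagery over a plot grid with row
    structure and Beer-law gap-fraction mixing), resamples imagery to a
    ladder of coarser resolutions by the nearest-neighbour rule,
    computes canonical vegetation/spectral indices and gray-level
    co-occurrence matrix (GLCM) texture statistics with their
    normalized-difference combinations, screens features by correlation
    with LAI within and across growth stages, fits multiple stepwise
    regression and random-forest models on a 2:1 plot split, parses
    printed linear LAI equations, and maps LAI pixel by pixel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    randomForest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
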
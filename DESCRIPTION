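Package: groovealign
Title: Alignment and Groove Containment of Microvessel-Like Structures on
    Patterned Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how hundred-micron-scale substrate architecture controls
    the position and orientation of self-assembled microcapillary-like structures
    in confocal fluorescence images. Provides parametric models of grooved and
    ridged bioceramic substrates, a synthetic confocal stack generator with
    ground truth, the image preparation chain (maximum projection, rotation and
    cropping, rolling-ball background subtraction, auto-contrast, Phansalkar
    local thresholding, small-particle removal), Fourier-spectrum orientation
    analysis with the Degree of Alignment (DOA) statistic, depth-profile groove
    detection with the Degree of Containment (DOC) statistic, and nonparametric
    group comparison (Kruskal-Wallis with Dunn's post-hoc test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
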
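Package: rootquant
Title: Semi-Automated Quantification of Arbuscular Mycorrhizal Root
    Colonization from Stained Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies arbuscular mycorrhizal (AM) fungal colonization of
    plant roots from brightfield micrographs of blue-stained root segments.
    Implements two complementary segmentation engines: a global
    brightness-thresholding pipeline that isolates the root from the
    background and measures the dark (stained) area fraction (the t-index),
    and a trainable per-pixel classifier built on a 25-channel filter bank
    (Gaussian, Sobel-of-Gaussian, Gabor and Hessian features) that labels
    colonized tissue, uncolonized root tissue and background (the ml-index).
    Includes Trouvelot six-class scoring of per-image colonization
    percentages, a synthetic stained-root micrograph generator with ground
    truth masks for validation, and an evaluation layer producing per-class
    descriptive statistics, one-way ANOVA (from raw values or published
    group summaries), Bonferroni pairwise post hoc comparisons, polynomial
    regression fits and model-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jpeg,
    png,
    randomForest,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
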
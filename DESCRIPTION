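Package: hyphacover
Title: Quantification of Bacterial Adhesion to Candida albicans Hyphae from
    Two-Channel Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated image-analysis pipeline that measures how much of
    the hyphal surface of Candida albicans is covered by fluorescently
    labeled bacteria. Hyphae are segmented from bright-field images by
    Gaussian smoothing, Sobel edge detection, directional morphological
    closing, IsoData auto-thresholding and directional opening; bacteria are
    segmented from a fluorescence focal stack by rolling-ball background
    subtraction, percentile contrast enhancement, maximum-intensity
    projection and a fixed intensity threshold. The headline statistic is
    the percentage of hyphal area overlapped by the bacterial mask. The
    package also ships a synthetic two-channel micrograph generator with
    pixel-level ground truth for benchmarking, batch processing over sample
    manifests, and the group statistics used for such assays (one-way ANOVA
    with Holm-Sidak multiple comparisons versus a control strain, plus
    plate-reader fluorescence normalizations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
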
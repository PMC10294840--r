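Package: cornealga
Title: Genetic-Algorithm Selection of CNN Feature Maps for Corneal Ulcer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for transfer-learning image
    classification: intermediate layers of a fixed ResNet-18 backbone are
    probed, every feature map is reduced to its spatial mean, and a genetic
    algorithm searches fixed-size subsets of maps whose linear-SVM accuracy
    is highest. Includes the full evaluation protocol (layer sweep over 67
    candidate layers, repeated stratified 70/30 splits, descriptive
    statistics, exact Wilcoxon signed-rank comparisons, percent-gain and
    relative computational-time reporting) and a synthetic-data module with
    planted informative channels and toy stained-eye images so every stage
    is testable without any image download or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
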
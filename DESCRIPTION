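Package: cbirqe
Title: Content-Based Image Retrieval with Class-Centroid Query Expansion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based retrieval for labelled medical image collections
    (CT, MRI) using Euclidean nearest-neighbour ranking over deep or
    hand-crafted feature vectors, with an automatic two-stage class-centroid
    query-expansion search: a rapid per-class top-k search with the original
    query, centroid (mean-vector) expansion of each class's top-ranked images,
    selection of the expansion closest to the query, and a final full-database
    search with the selected centroid. Includes the standard retrieval
    evaluation protocol (every image as query, relevance = same class) with
    average retrieval precision, average retrieval rate and F-score at one or
    more cutoffs, overall and per class; pluggable feature extractors with a
    deterministic histogram descriptor that needs no pretrained weights;
    synthetic Gaussian-cluster feature databases and synthetic image trees for
    benchmarking; a lossless on-disk feature store; and a command-line
    interface tying extraction, search, evaluation and simulation together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    arrow,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
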
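Package: somscore
Title: Cluster-Number Selection for Self-Organizing Maps with
    Discriminant-Score Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for choosing the number of posture clusters when grouping
    skeleton keypoint time series with one-dimensional Kohonen self-organizing
    maps (SOMs). Implements online SOM training under cosine or Euclidean
    winner matching, five internal cluster-validity indices in the variants
    used for posture work (silhouette coefficient, centroid-variant Dunn
    index, sum-form Davies-Bouldin index, Calinski-Harabasz index, and
    quantization error), and a per-frame discriminant score: the normalized
    inverse distance from a frame to every cluster centroid, tracked over
    time as a trajectory whose peaks, dwell times and steep edges expose
    posture transitions. A peak-based selection rule turns those trajectories
    into a recommended cluster count. Includes a synthetic skeleton-sequence
    generator with ground-truth segment labels, readers and writers for wide
    CSV and JSON-lines skeleton formats, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
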
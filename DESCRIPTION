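Package: lrcmc
Title: Laplacian Rank Constrained Multiview Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-step multiview clustering by joint graph learning. Each view
    (e.g. one omics layer measured on the same samples) is summarised by a
    sparse adaptive-neighbor affinity graph; the per-view graphs are fused
    into a weighted consensus graph whose Laplacian is rank-constrained so
    that the graph has exactly c connected components, and cluster labels are
    read directly off those components. Includes clustering quality metrics
    (accuracy under optimal label matching, normalized mutual information,
    purity), a synthetic multiview data generator with known ground truth,
    and delimited-text / MatrixMarket input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
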
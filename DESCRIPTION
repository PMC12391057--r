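Package: simnets
Title: Similarity Networks for Simultaneously Recorded Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative functional subnetworks in simultaneously
    recorded spiking neural populations by comparing the intrinsic geometry
    of each neuron's spike-train output space. Each neuron is summarized by
    an S x S matrix of Victor-Purpura edit distances among its S spike
    trains (its "computational fingerprint"); fingerprints are compared
    across neurons with Pearson correlation to form an N x N computational
    similarity matrix, embedded into a low-dimensional map with
    PCA-initialized t-SNE, and clustered with k-means under silhouette-based
    model selection. Cluster significance is assessed with a Mantel-style
    permutation test that shuffles each neuron's distance matrix rows and
    columns jointly to build an empirical null of silhouette scores.
    Includes a ground-truth population simulator (rate, temporal, and mixed
    coding schemes) so the full pipeline can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rtsne,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
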
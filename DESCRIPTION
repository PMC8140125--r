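Package: keyregnet
Title: Network-Based Identification of Disease Signature Genes and Key Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for network-based screening of disease
    gene-expression data. Implements differential-expression screening with a
    two-dataset consensus rule, cross-disease signature-gene overlap,
    protein-protein interaction network topology (degree distribution,
    clustering, neighbourhood connectivity, betweenness, closeness and
    eigenvector centrality) with power-law characterisation by discrete
    maximum likelihood (Clauset-style MLE with Kolmogorov-Smirnov x_min
    selection) and log-log regression, degree-preserving and Erdos-Renyi null
    models, recursive leading-eigenvector community decomposition with
    Constant-Potts-Model Hamiltonian energy and key-regulator tracing,
    local-community-paradigm (LCP) link statistics, and cross-species
    interolog mapping. Ships seeded synthetic-data generators (planted
    hierarchical networks and paired expression series) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
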
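Package: ppivar
Title: Differential Variation of Hubs and Bottlenecks in Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates protein-protein interaction tables from several
    source dialects into one undirected simple network, computes degree and
    betweenness centrality (Brandes accumulation), partitions proteins into
    hub/bottleneck topological classes by quantile cut-offs, estimates
    per-protein non-synonymous SNP density (dN) by codon-site enumeration
    with optional CpG exclusion, and tests for differential variation
    between hub-non-bottlenecks and non-hub-bottlenecks with rank tests,
    domain randomization nulls and node/edge subsampling robustness checks.
    A synthetic-data module generates complete input bundles with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    seqinr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
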
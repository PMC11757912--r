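Package: netprox
Title: Batch-Aware Differential Expression and Network Proximity Analysis of
    Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Netprox", "Developers", email = "netprox@example.org",
           role = c("aut", "cre"))
Description: An integration pipeline for case/control bulk RNA-seq studies
    spanning several batches: median-of-ratios normalization, empirical-Bayes
    location/scale batch adjustment, moderated-t differential expression with
    Benjamini-Hochberg control, weighted gene co-expression networks with the
    topological overlap measure, a shortest-path core-proximity score that
    ranks genes by closeness to a designated core set, protein-protein
    interaction network topology statistics with hub/nonhub classification and
    greedy modularity clustering, and pairwise expression-correlation
    validation.  Ships a synthetic-data generator with known ground truth so
    the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
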
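Package: ncoocnet
Title: Co-Occurrence Network Inference and Community Analysis for
    N-Cycle Functional-Gene OTU Tables
Version: 0.1.0
Authors@R: person("ncoocnet", "Developers", role = c("aut", "cre"),
    email = "ncoocnet@example.org")
Description: Infers microbial co-occurrence and co-exclusion networks from
    OTU-by-sample count tables using thresholded Spearman scores with a
    compositionality-aware (renormalized) permutation null and bootstrap
    stability filtering (the ReBoot scheme), followed by Brown p-value
    merging and Benjamini-Hochberg correction.  Provides network topology
    summaries and keystone-taxon detection under joint
    degree/closeness/betweenness criteria, alpha-diversity indices,
    Bray-Curtis ordination (PCoA), PERMANOVA, Mantel tests and
    diversity-environment correlation matrices, plus a synthetic
    compositional-community generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
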
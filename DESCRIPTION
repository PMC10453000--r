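Package: oncogrn
Title: Cancer Type-Specific Gene Regulatory Networks from Expression Data
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs cancer type-specific gene regulatory networks (GRNs)
    from non-negative expression matrices restricted to a gold-standard list of
    transcription factor (TF) to target pairs, detects subnetworks by community
    detection, assigns them to cancer types, trains one-vs-rest random forest
    classifiers, quantifies GRN establishment (GRN status) in query samples,
    ranks network-influencing TFs, and relates single-gene expression to
    patient survival through a quartile-bounded best-cutoff scan with FDR
    gating. Includes a synthetic-data generator that emulates a multi-class
    training corpus with planted TF hubs, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
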
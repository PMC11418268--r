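Package: visitrx
Title: Visit-Level Medication Combination Recommendation from Electronic Health Records
Version: 0.1.0
Authors@R: person("Maintainer", "visitrx", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recommending medication combinations at the level of
    individual hospital visits. Implements set-transformer encoders over
    diagnosis and procedure codes, a graph isomorphism network (GIN) encoder
    for drug molecular substructures, a cross-attention plus multi-head
    self-attention (CA-MHSA) fusion block, a GRU over historical
    prescriptions, and a combined multi-label binary cross-entropy and
    drug-drug interaction (DDI) loss, trained visit-by-visit. Includes a
    synthetic EHR cohort generator with planted disease-to-drug rules for
    benchmarking, multi-label evaluation metrics (Jaccard, F1, PRAUC, DDI
    rate) with a bootstrap protocol, visit-count-stratified reports, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
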
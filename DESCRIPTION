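Package: flavoromics
Title: Volatile Flavoromics from GC-MS Peak Tables: ROAV Flavor Networks
    and VIP-Gini Signature Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for volatile organic compound (VOC) profiles
    measured by headspace GC-MS on replicated fruit samples.  Computes
    per-sample relative contents by area normalization, aggregates them into
    group profiles (mean +/- SD), and identifies key flavor compounds by
    relative odor activity values (ROAV) computed from odor thresholds in
    water.  Key compounds and their odor descriptors form a bipartite flavor
    network with descriptor weights given by summed ROAVs.  Signature
    differential compounds between two groups are screened by fusing
    OPLS-DA variable importance (VIP, implemented from scratch with
    cross-validated Q2 and permutation validation) with random-forest Gini
    importance through min-max normalization and averaging, applying the
    VIP >= 1 and fused score > 0.5 criteria.  Ships a synthetic peak-table
    generator with planted discriminant compounds for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
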
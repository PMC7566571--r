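Package: isomiRscope
Title: IsomiR Cataloguing, Seed-Site Target Prediction and Host-Gene
    Surrogate Analysis for Small-RNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to catalogue 5' and 3' isomiRs from small-RNA read
    pools against hairpin references, call nontemplated 3' additions,
    group reads by seed, derive canonical seed-match site motifs
    (6mer, 7mer-A1, 7mer-m8, 8mer) and scan 3'UTRs for predicted
    targets, compute ranked-list hypergeometric word-enrichment
    landscapes and target fold-change statistics from differential
    expression tables, and run a host-gene surrogate inverse-correlation
    analysis across a compendium of expression studies. Includes a
    synthetic-data generator with ground-truth manifests so every stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
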
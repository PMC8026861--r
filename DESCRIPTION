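Package: megasignet
Title: Signed Literature Networks and Cross-Dataset Expression Mega-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connecting two diseases through signed, literature-derived
    gene relations and case-control expression data. Provides quality control and
    set accounting for signed relation tables, construction of protective
    disease-to-disease regulatory networks, a per-gene cross-dataset mega-analysis
    with Cochran's Q heterogeneity testing and fixed/random-effects model selection
    (DerSimonian-Laird), gene-set over-representation analysis with
    Benjamini-Hochberg false discovery control, signed shortest-path exploration
    with polarity composition, and a synthetic-data generator with planted truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
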
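Package: lncora
Title: lncRNA-Aware Over-Representation Analysis of Differential Expression
Version: 0.1.0
Authors@R:
    person("lncora", "maintainers", email = "lncora@example.org", role = c("aut", "cre"))
Description: Derives differentially expressed (DE) genes and lncRNAs from
    replicate FPKM tables using fold-change, expression-floor and replicate
    variability filters; associates DE lncRNAs with overlapping or nearby
    protein-coding genes ("lncGenes", 5 kb window by default); and tests GO
    and KEGG term over-representation with both the classical hypergeometric
    tail and an lncGene-augmented statistic, followed by pruning of redundant
    significant GO parent terms.  Includes a fully self-contained synthetic
    data generator (annotations, expression, term maps, ground truth) and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
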
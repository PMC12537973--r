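Package: depscreen
Title: Entity-Specific Vulnerability Screening on CRISPR Dependency Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential gene-dependency screening on gene-by-cell-line
    CRISPR knockout effect matrices (DepMap Chronos style): per-gene
    median-difference and Welch t statistics between a target cancer entity
    and a pan-cancer background, top-K candidate selection, hypergeometric
    pathway over-representation with Benjamini-Hochberg correction, and a
    dual essentiality-threshold filter yielding a ranked candidate table.
    Companion tools cover the downstream analyses such screens feed:
    median-based log2 fold-change differential expression with unpaired
    t-tests, 2^(-ddCt) relative quantification for qPCR, and median-split
    Kaplan-Meier survival with Mantel-Cox log-rank comparison. A synthetic
    data module generates every input with known ground truth (planted
    selective essentials, planted pathway enrichment, planted expression
    effects, covariate-dependent hazards) so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
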
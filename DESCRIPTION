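Package: biotinpaint
Title: Structural Enrichment Analysis of In Vivo Biotinylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for re-purposing proximity-labelling proteomics (BioID,
    APEX2, NHS-biotin "biotin painting") as a probe of protein structure in
    vivo. Converts per-residue disorder predictions into intrinsically
    disordered region (IDR) interval sets with union and quorum-consensus
    combination, tests whether biotinylation and endogenous PTM sites are
    enriched inside IDRs with a residue-composition-aware exact binomial
    test, classifies proteins as folded / partially folded / unfolded and
    compares biotin counts across classes, performs bias-corrected GO
    category enrichment via the Wallenius noncentral hypergeometric
    distribution with an isotonic probability weighting function, and
    analyses TMT labelling time courses with empirical-Bayes moderated
    t-tests. A synthetic-data generator emulates every input so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
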
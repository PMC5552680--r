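Package: chardir
Title: Characteristic-Direction Analysis of Tumorigenic Versus Healthy
    Dividing Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to contrast cancer cell lines with healthy dividing
    cells from bulk expression data.  Fits a shrinkage-regularised linear
    discriminant (the "characteristic direction") in gene-expression
    space, assesses per-gene contributions by label permutation with
    Benjamini-Hochberg false-discovery control, and projects independent
    samples onto the direction.  Transcription-factor activities are
    estimated as regulon-restricted projections and correlated across
    samples.  RNA-seq companions cover Welch-t differential expression on
    RPKM matrices, gene-set expression sums, Spearman screens against
    transcription-factor genes, and Fisher-exact overlap enrichment of
    consensus gene lists.  A constraint-based module fits parsimonious
    flux distributions to measured metabolite exchange rates on a
    stoichiometric model and attributes ATP production to lactate
    fermentation and branched-chain amino-acid catabolism.  Synthetic
    generators for every input make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
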
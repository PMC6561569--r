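Package: wgdtv
Title: Dating Gene Duplications with 4dTv, Reconciliation and Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dating and characterising gene-duplication events in
    fish and other eukaryote lineages from transcriptome- or genome-derived
    gene families. Implements transcript and alignment filtering (DUST
    low-complexity score, length, expression, gap fraction), protein-guided
    codon alignments, fourfold-degenerate transversion (4dTv) distances
    between paralogue pairs with the -ln(1-2d)/2 saturation correction,
    parsimony LCA reconciliation of gene trees against a species tree with
    per-branch duplication assignment, a rule-based synteny classifier of
    paralogue pairs (close, some synteny, no synteny, no info, conflicting),
    lognormal mixture-model dating of paralogue-age distributions, and
    Fisher exact enrichment with Benjamini-Hochberg correction. A built-in
    simulator plants whole-genome duplications, tandem segmental
    duplications, and delayed-rediploidization signals with known ground
    truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    mclust,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
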
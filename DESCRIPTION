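Package: ctermbias
Title: C-Terminal Sequence Composition and Its Impact on Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analyses of the composition of the C-terminal region of bacterial
    protein sequences and of its consequences for protein expression.
    Computes position-specific amino-acid and codon composition biases against
    the bulk of the sequence with exact tests and false-discovery-rate
    control, pairwise epistasis between the last two residues, stop-codon
    context and stratified bias tables, position-resolved amino-acid
    substitution rates from three-taxon maximum-parsimony reconstruction,
    quantification of expression effects of randomized C-terminal sequences
    from methylation-sensitive digestion read counts (DAMratio), and protein
    degradation-rate fitting from reporter shut-off time courses. Includes
    synthetic-data generators with known ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
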
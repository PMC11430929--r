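Package: phyloepi
Title: Phylo-Epigenetic Analysis of CpG Dinucleotides in Aligned CpG Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies CpG dinucleotide sites across a multi-species
    alignment of concatenated CpG islands, counts the CpG mutation
    spectrum (CG to TG, CA, GG, CC, CT and AG), recodes the alignment to
    a binary A/T representation of CpG presence or absence, and builds,
    calibrates and compares UPGMA ultrametric trees from the full versus
    the recoded alignment.  Includes a context-dependent
    sequence-evolution simulator with elevated CpG deamination
    transition rates so that every stage of the pipeline can be
    exercised on data with a known generating tree.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
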
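Package: symbiopoly
Title: Cryptic Endosymbiont Strain and Haplotype Diversity from Cloned
    MLST Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for uncovering cryptic Wolbachia strain and
    haplotype diversity from cloned multilocus sequence typing (MLST)
    amplicons sequenced after artificial host transfer. Calls single
    nucleotide substitutions in clone reads against a strain consensus,
    classifies recurrent versus singleton variants, estimates the
    polymerase/cloning error baseline from control re-sequencing sets,
    computes per-kilobase SNP frequencies with baseline correction and
    contingency tests (chi-squared with Yates correction, Fisher exact),
    annotates codon effects including premature stop codons, estimates
    Nei-Gojobori (1986) path-counting dN/dS with Jukes-Cantor correction,
    types strains at diagnostic sites with prevalence-switch detection,
    predicts in-silico restriction fragment fingerprints, scores ovary
    fecundity classes, and simulates haplotype populations through a
    transfer bottleneck with Wright-Fisher drift and clone re-sequencing
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
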
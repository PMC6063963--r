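Package: pairscreen
Title: Pairwise Guide-Target Library Screens of CRISPR-SaCas9 Specificity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design, simulation, and analysis of pairwise guide-target library
    screens that measure Staphylococcus aureus Cas9 (SaCas9) genome-editing
    specificity in pooled synthetic cassettes. Provides error-correcting
    quaternary Hamming DNA barcodes (encode, decode with single-substitution
    correction, composition filters, minimum-edit-distance subsampling),
    construction of guide-target variant libraries (single and double
    mismatches, transversions, DNA/RNA bulges, scrambled controls), a
    paired-end read simulator with known ground truth, randomized-barcode
    (rBC) whitelisting with indel-rate quantification and off:on-target
    ratios, and a Bayesian multiplicative mismatch-penalty model used to
    score and rank candidate off-target sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
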
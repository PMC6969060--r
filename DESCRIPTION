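Package: clonetrace
Title: Clonal Evolution Analysis of Patient-Matched Primary and Metastatic Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs subclonal composition and clone fates across
    patient-matched tumor lesions from somatic variant read counts.
    Implements copy-number-aware correction of variant allele frequencies
    (duplication, deletion, copy-neutral LOH and male-X rules), tumor-purity
    scaling, an expectation-maximization Gaussian mixture clustering of
    corrected allele frequencies with BIC model selection, cross-lesion
    clone-fate classification (maintained / lost / emergent), B-allele
    frequency based arm-level copy-number calling, and mutational-signature
    exposure refitting over the 96 trinucleotide contexts. A forward
    simulator generates multi-lesion synthetic patients with known clone
    structure, copy-number events, purity and binomial read sampling so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
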
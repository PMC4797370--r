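Package: asmarker
Title: Allele-Specific SNP/Indel Marker Design for Marker-Assisted Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and in-silico validation of allele-specific PCR-gel-based
    markers for tracking target gene alleles in plant breeding. Screens
    donor-specific SNP and indel polymorphisms between allele sequences,
    designs indel-spanning, tetra-primer ARMS, separated allele-specific and
    tri-primer (gap-reduction) markers with engineered 3'-proximal mismatches,
    predicts amplicons under an ARMS extension-blocking mismatch model,
    simulates gel/capillary band resolution with PP/PN/NN genotype calling,
    and classifies varieties into named haplotype classes from defining-site
    genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
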
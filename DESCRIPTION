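Package: bdaconfirm
Title: Confirmation of Low-Frequency Somatic Variants by Blocker
    Displacement Amplification qPCR and Sanger Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses orthogonal confirmation of putative
    somatic variants called at or below 5% variant allele frequency (VAF)
    in whole exome sequencing. Implements the blocker displacement
    amplification (BDA) enrichment model, qPCR delta-Cq quantification
    and VAF estimation, assay validation against matched positive and
    negative controls, three-outcome classification of enriched Sanger
    calls (confirmed, absent, misidentified), and cohort-level
    confirmation reporting stratified by sample type, gene class, VAF
    bracket, functional category and alteration type. A synthetic-cohort
    generator emulates mirrored fresh-frozen/FFPE tumor exomes with
    FFPE deamination artifacts, binomial read sampling and noisy Cq
    values, providing ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
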
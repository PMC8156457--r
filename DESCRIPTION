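Package: cfmito
Title: Cell-Free Mitochondrial DNA Screening from Low-Pass Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, variant calling and filtration, heteroplasmy
    classification, haplogroup assignment and cohort-level statistics for
    cell-free mitochondrial DNA (cf-mtDNA) obtained as a by-product of
    low-pass whole-genome sequencing, as performed in non-invasive prenatal
    testing (NIPT). Includes a synthetic cf-mtDNA cohort generator with
    known ground truth (tissue mixtures, transport-dependent leukocyte
    leakage, heteroplasmy, homopolymer-concentrated indel errors) so that
    every stage of the pipeline can be exercised and validated without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
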
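Package: xenoquant
Title: Quantification of Human Tumor Burden in Zebrafish Xenografts from
    qPCR and Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for embryonic zebrafish liver-cancer
    xenograft experiments in an acetylcholinesterase (ache) mutant
    background. Provides qPCR well-table import and quality control
    (DNA purity/concentration thresholds, melting-curve primer-dimer
    exclusion, non-detect handling), allele-specific genotype calling of
    single embryos from Ct differences, AluYb8-based human tumor DNA
    quantification with copy-number-corrected delta-Ct normalization,
    standard-curve fitting with amplification efficiency and empirical
    limit of detection, delta-delta-Ct relative expression, image-based
    tumor-area segmentation and dispersed-cell metastasis scoring, the
    study-level group-comparison statistics, and a synthetic-cohort
    generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
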
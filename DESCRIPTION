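Package: chorigin
Title: Bayesian Classification of Clonal Hematopoiesis, Tumor, and Germline
    Variants from Paired Blood and Marrow Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies candidate somatic variants observed in paired
    peripheral-blood (PB) and bone-marrow (BM) samples into clonal
    hematopoiesis (CH), tumor, or germline origin with a Bayesian model of
    paired allele counts. Beta likelihoods of the variant allele fraction
    are combined with site-specific two-way contamination corrections
    (tumor-in-normal fraction in blood, blood fraction in marrow) derived
    from tumor purity, ploidy, and local allele-specific copy number.
    Includes the upstream candidate-filtering rules for CH driver variants,
    longitudinal clone-dynamics statistics for serial samples, and a
    synthetic paired-cohort generator with ground-truth origin labels for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, pracma
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
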
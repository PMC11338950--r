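Package: phosmat
Title: Quantitative TMT Phosphoproteomics of Sperm Epididymal Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for multiplexed (TMT) quantitative
    phosphoproteomics of mouse sperm maturing along the epididymis (caput,
    corpus, cauda). Implements class-I phosphosite filtering by localization
    probability, row-mean intensity normalization with protein-abundance
    calibration of phosphosite levels, two-group differential phosphorylation
    statistics (Student's t-test with fold-change classification), motif-based
    kinase-substrate prediction over +/-7 flanking windows with
    false-positive-rate calibrated cutoffs and Fisher's exact kinase
    enrichment, generic hypergeometric over-representation analysis against
    GMT gene sets, and an inhibitor-versus-maturation overlap analysis.
    Includes a synthetic-data generator with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
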
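Package: vascreen
Title: Marker-Guided Vascular Gene Screening and Radiogenomic Association in Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("vascreen", "maintainers", email = "maintainers@vascreen.org", role = c("aut", "cre"))
Description: Identifies endothelial-cell-enriched genes in bulk tumor
    RNA-seq by correlation with a vascular marker panel (CDH5, CLDN5, VWF),
    scores each enriched gene for association with MRI contrast enhancement
    by differential correlation between the most- and least-enhancing tumors,
    and stratifies patient survival by the enhancing-volume fraction
    (Kaplan-Meier, log-rank, Cox). Ships a synthetic cell-type-mixture
    generator with planted ground truth for end-to-end validation, plus a
    small command-line pipeline over TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
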
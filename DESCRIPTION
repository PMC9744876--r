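Package: xenores
Title: Cross-Species Filtering, Signature Scoring and Resistance Endpoints
    for Xenograft RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("BMX", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dual-species (human tumor / mouse stroma)
    xenograft sequencing studies of drug resistance. Provides gene-level
    cross-species contamination filtering of combined-annotation count
    matrices using species-pure control libraries, median-of-ratios
    normalization with a log variance-stabilizing transform, gene-signature
    scoring with median stratification and survival analysis, a signed
    inverse-adjusted-p GSEA rank statistic with the classic running-sum
    enrichment score and hypergeometric over-representation, a paired
    control-versus-resistant somatic variant persistence filter with
    expression gating, and pre-clinical tumor-burden endpoint calls
    (progression-free survival, resistance onset, metastasis incidence)
    with the accompanying two-group and survival statistics. A seeded
    synthetic-data module generates every input with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
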
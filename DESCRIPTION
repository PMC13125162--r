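Package: vusreclass
Title: Missense VUS Reclassification with Calibrated Computational Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the impact of ClinGen-calibrated variant effect
    predictor (VEP) score thresholds on the classification of clinically reported
    missense variants. Implements the ACMG/AMP 2015 evidence-combining rules with
    modifiable criterion strengths, maps raw predictor scores (REVEL, VARITY,
    AlphaMissense, ESM1b, BayesDel, VEST4, SIFT, PolyPhen-2) to PP3/BP4 evidence
    at calibrated strength levels, swaps that evidence into curated evidence
    profiles and recomputes classifications, and summarises reclassification
    rates, inter-predictor concordance, and cohort-level association statistics.
    Includes a synthetic-cohort generator with a shared latent pathogenicity
    factor so the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2
Config/testthat/edition: 3
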
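# Calibrated score-threshold configuration for the eight shipped missense
# predictors. Intervals map raw scores to PP3/BP4 evidence at an ACMG strength
# level; thresholds are inclusive on the evidence-bearing side (a score equal
# to a published threshold earns that strength). Numbers are transcribed from
# the ClinGen Sequence Variant Interpretation recalibration publications named
# in each predictor's provenance string; tiers whose published value could not
# be transcribed with confidence are omitted rather than approximated, so this
# file is deliberately swappable.
predictors:
  REVEL:
    orientation: higher_is_deleterious
    range: [0.0, 1.0]
    provenance: >-
      Pejaver et al. 2022, Am J Hum Genet 109:2163-2177 (ClinGen SVI
      calibration of computational evidence for PP3/BP4).
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.003, hi_incl: true,  assign: BP4, strength: VeryStrong}
      - {lo: 0.003, lo_incl: false, hi: 0.016, hi_incl: true,  assign: BP4, strength: Strong}
      - {lo: 0.016, lo_incl: false, hi: 0.183, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: 0.183, lo_incl: false, hi: 0.290, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: 0.290, lo_incl: false, hi: 0.644, hi_incl: false, assign: NONE}
      - {lo: 0.644, lo_incl: true,  hi: 0.773, hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.773, lo_incl: true,  hi: 0.932, hi_incl: false, assign: PP3, strength: Moderate}
      - {lo: 0.932, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: PP3, strength: Strong}
  VARITY:
    orientation: higher_is_deleterious
    range: [0.0, 1.0]
    provenance: >-
      Bergquist et al. 2025, Genet Med (ClinGen SVI calibration of additional
      computational tools; VARITY_R model).
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.049, hi_incl: true,  assign: BP4, strength: Strong}
      - {lo: 0.049, lo_incl: false, hi: 0.116, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: 0.116, lo_incl: false, hi: 0.231, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: 0.231, lo_incl: false, hi: 0.674, hi_incl: false, assign: NONE}
      - {lo: 0.674, lo_incl: true,  hi: 0.814, hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.814, lo_incl: true,  hi: 0.925, hi_incl: false, assign: PP3, strength: Moderate}
      - {lo: 0.925, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: PP3, strength: Strong}
  AlphaMissense:
    orientation: higher_is_deleterious
    range: [0.0, 1.0]
    provenance: >-
      Bergquist et al. 2025, Genet Med (ClinGen SVI calibration of additional
      computational tools).
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.070, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: 0.070, lo_incl: false, hi: 0.169, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: 0.169, lo_incl: false, hi: 0.792, hi_incl: false, assign: NONE}
      - {lo: 0.792, lo_incl: true,  hi: 0.906, hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.906, lo_incl: true,  hi: 0.972, hi_incl: false, assign: PP3, strength: Moderate}
      - {lo: 0.972, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: PP3, strength: Strong}
  ESM1b:
    orientation: lower_is_deleterious
    range: [-30.0, 5.0]
    provenance: >-
      Bergquist et al. 2025, Genet Med (ClinGen SVI calibration of additional
      computational tools). ESM1b is a log-likelihood ratio; more negative is
      more damaging, so orientation is lower_is_deleterious.
    intervals:
      - {lo: -30.0,  lo_incl: true,  hi: -11.77, hi_incl: true,  assign: PP3, strength: Strong}
      - {lo: -11.77, lo_incl: false, hi: -10.22, hi_incl: true,  assign: PP3, strength: Moderate}
      - {lo: -10.22, lo_incl: false, hi: -7.96,  hi_incl: true,  assign: PP3, strength: Supporting}
      - {lo: -7.96,  lo_incl: false, hi: -6.02,  hi_incl: false, assign: NONE}
      - {lo: -6.02,  lo_incl: true,  hi: -4.99,  hi_incl: false, assign: BP4, strength: Supporting}
      - {lo: -4.99,  lo_incl: true,  hi: 5.0,    hi_incl: true,  assign: BP4, strength: Moderate}
  BayesDel:
    orientation: higher_is_deleterious
    range: [-1.3, 0.8]
    provenance: >-
      Pejaver et al. 2022, Am J Hum Genet 109:2163-2177 (BayesDel without
      allele frequency, noAF).
    intervals:
      - {lo: -1.3,  lo_incl: true,  hi: -0.36, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: -0.36, lo_incl: false, hi: -0.18, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: -0.18, lo_incl: false, hi: 0.13,  hi_incl: false, assign: NONE}
      - {lo: 0.13,  lo_incl: true,  hi: 0.27,  hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.27,  lo_incl: true,  hi: 0.50,  hi_incl: false, assign: PP3, strength: Moderate}
      - {lo: 0.50,  lo_incl: true,  hi: 0.8,   hi_incl: true,  assign: PP3, strength: Strong}
  VEST4:
    orientation: higher_is_deleterious
    range: [0.0, 1.0]
    provenance: >-
      Pejaver et al. 2022, Am J Hum Genet 109:2163-2177.
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.302, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: 0.302, lo_incl: false, hi: 0.449, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: 0.449, lo_incl: false, hi: 0.764, hi_incl: false, assign: NONE}
      - {lo: 0.764, lo_incl: true,  hi: 0.861, hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.861, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: PP3, strength: Moderate}
  SIFT:
    orientation: lower_is_deleterious
    range: [0.0, 1.0]
    provenance: >-
      Pejaver et al. 2022, Am J Hum Genet 109:2163-2177. SIFT scores tolerance
      probability; lower is more deleterious.
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.001, hi_incl: true,  assign: PP3, strength: Moderate}
      - {lo: 0.001, lo_incl: false, hi: 0.08,  hi_incl: true,  assign: PP3, strength: Supporting}
      - {lo: 0.08,  lo_incl: false, hi: 0.327, hi_incl: false, assign: NONE}
      - {lo: 0.327, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: BP4, strength: Supporting}
  PolyPhen-2:
    orientation: higher_is_deleterious
    range: [0.0, 1.0]
    model_variant: HVAR
    provenance: >-
      Pejaver et al. 2022, Am J Hum Genet 109:2163-2177 (PolyPhen-2 HVAR
      classifier).
    intervals:
      - {lo: 0.0,   lo_incl: true,  hi: 0.009, hi_incl: true,  assign: BP4, strength: Moderate}
      - {lo: 0.009, lo_incl: false, hi: 0.113, hi_incl: true,  assign: BP4, strength: Supporting}
      - {lo: 0.113, lo_incl: false, hi: 0.978, hi_incl: false, assign: NONE}
      - {lo: 0.978, lo_incl: true,  hi: 0.999, hi_incl: false, assign: PP3, strength: Supporting}
      - {lo: 0.999, lo_incl: true,  hi: 1.0,   hi_incl: true,  assign: PP3, strength: Moderate}
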
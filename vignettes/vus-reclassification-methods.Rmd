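---
title: "Methods: calibrated in-silico evidence and missense VUS reclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated in-silico evidence and missense VUS reclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusreclass)
```

## The problem

Missense variants reported from clinical sequencing are classified under the
ACMG/AMP 2015 framework into Pathogenic (P), Likely pathogenic (LP), uncertain
significance (VUS), Likely benign (LB) and Benign (B) by combining coded
evidence criteria. Under the original guideline, computational (in-silico)
predictions contribute only the weakest evidence level, through the codes PP3
(predicted deleterious) and BP4 (predicted benign). ClinGen's recalibration of
variant effect predictors (VEPs) against reference variant sets showed that
several predictors' scores can justify stronger evidence — up to Strong or
Very strong — at specific score thresholds.

`vusreclass` asks the operational question a diagnostic laboratory faces: *if
the calibrated thresholds replace the legacy Supporting-level PP3/BP4 usage in
existing curated classifications, how many VUS move?* The pipeline swaps
calibrated PP3/BP4 assignments into curated evidence profiles one predictor at
a time, recombines under the 2015 rules, and summarises reclassification
rates, inter-predictor concordance, and cohort statistics.

## The combining engine

`combine_evidence()` counts effective strengths per polarity and applies the
2015 combining rules. Counting is *code-agnostic*: a criterion's effective
strength, not its code, determines the slot it fills, so `PP3_Strong` counts
exactly as PS1 would. This is the mechanism implied by strength-modified
labels such as `PP3_Strong` or `BP4_VeryStrong` and is standard ClinGen SVI
practice.

Decisions the published table leaves open, and how this package resolves them:

* **Conflicting evidence.** If at least one rule fires on each polarity the
  result is VUS, the guideline's stated default.
* **A single Strong benign criterion.** The strict 2015 table leaves `1xBS`
  unclassified. Laboratory practice treats it as Likely benign, and the
  VUS→LB flows produced by a lone BP4 upgrade require it, so the engine ships
  with `single_bs_is_lb = TRUE`. The rule is *suppressed when any pathogenic
  criterion is applied*: a profile such as `PS1,BS1` is contradictory evidence
  and stays VUS rather than becoming LB through the extension. Both the flag
  and this gating are testable via `acmg_options()`.
* **Two Very-strong items.** Not covered by the published table (which
  assumes a single PVS1); the engine classifies `>=2` Very strong as
  Pathogenic, the only reading consistent with monotonicity.
* **Benign Moderate evidence.** The 2015 benign rules mention only Strong and
  Supporting; calibrated BP4 can be Moderate. A Moderate benign item satisfies
  any Supporting-benign requirement — without this, raising BP4 from
  Supporting to Moderate could *weaken* a Likely-benign call, violating
  monotonicity.
* **BA1** forces Benign even against pathogenic evidence
  (`ba1_overrides = TRUE`, switchable).
* **Stand-alone strength** is reserved for BA1; the profile validator rejects
  it elsewhere rather than inventing a counting rule for a pathogenic
  stand-alone item, which the 2015 catalogue does not define.
* **Duplicate codes** replace the previous entry (at most one entry per code),
  mirroring the replace-not-stack semantics of the evidence swap.

These choices make the classification monotone: raising any criterion's
strength, or adding a criterion, never moves the result toward the opposite
polarity's end of the tier order B < LB < VUS < LP < P. The test suite checks
the engine exhaustively against an independently transcribed rule table for
every profile of up to six criteria, plus randomized monotonicity sweeps.

## Calibrated score thresholds

The calibration table maps each predictor's score range onto ordered,
disjoint, jointly covering intervals, each assigning PP3 or BP4 at a strength
(or no evidence). Orientation is explicit per predictor: SIFT and ESM1b are
*lower-is-deleterious*, the other six shipped predictors the reverse.
Validation enforces coverage, disjointness, one-sided boundary inclusivity and
orientation-aware monotonicity (along the deleterious direction, BP4 weakens,
passes through the indeterminate region, then PP3 strengthens).

The shipped YAML (`default_calibration_path()`) transcribes the ClinGen
recalibration publications named in each predictor's provenance string.
Thresholds are inclusive on the evidence-bearing side because the source
calibrations state them as "score >= t" / "score <= t". Two transcription
caveats are deliberate: tiers whose published value could not be transcribed
with confidence are omitted rather than approximated, and the PolyPhen-2
entry declares the HVAR classifier (`model_variant`), the usual choice for
Mendelian diagnostics, since laboratory practice varies. The file is data,
not code: swapping in a different calibration requires no package change.

## The evidence swap

For one predictor, `reclassify_cohort()`:

1. decides eligibility — by default (`"baseline-insilico"`) only variants
   whose curated profile already applied PP3 or BP4 enter the analysis,
   mirroring the reanalysis design; `"all"` is available for sensitivity
   analysis;
2. maps the score through the calibration table;
3. removes any baseline PP3/BP4 and inserts the calibrated assignment
   (`revise_evidence()`), so in-silico evidence is replaced, never stacked,
   and PP3/BP4 never co-occur;
4. recombines and records the transition.

When the score falls in the indeterminate region the baseline PP3/BP4 is
*dropped* (the calibrated predictor supplies no evidence); the alternative
reading — keep the legacy Supporting entry — is available as
`retain_baseline_on_none = TRUE`. Missing and out-of-range scores exclude the
variant from that predictor's denominator (logged), rather than counting it
as unchanged; this is the conservative reading of per-predictor percentages
reported without an imputation procedure.

Curated records whose label disagrees with the engine's combination of their
stated evidence are kept *as reported* and flagged (`as_reported`), with the
reported label used as the transition's starting tier. This matters for the
shipped hearing-loss fixture: its six records carry a reconstructed
`BS1,BP4` profile (an assumption — the original non-computational evidence is
not public, hence the `_synthetic` filename suffix), which the engine alone
would call LB while the curated label is VUS.

The headline statistic, `reclassification_percentage()`, uses eligible
baseline-VUS outcomes with a present score as denominator. Coordinates are
1-based GRCh37/hg19 throughout; no liftover is in scope.

## Cohort statistics

* **Concordance** (`pairwise_concordance()`): among baseline VUS changed by
  either of two predictors, the share changed by both *to the same tier*
  (`destination_agnostic = TRUE` gives the weaker reading). Cells with an
  empty union are undefined, not 100%, and are counted separately —
  with small denominators this distinction dominates.
* **Odds ratios** (`fisher_exact_or()`): two-sided Fisher exact p-value
  (delegated to `stats::fisher.test`, i.e. the sum of hypergeometric
  probabilities at or below the observed table's); the point estimate is the
  *sample* OR ad/bc with a 95% Woolf logit interval, which is what reproduces
  the published genome-wide-vs-panels VUS estimate of 0.73 (0.61–0.86); the
  conditional-MLE estimate is returned alongside. Zero cells trigger the
  Haldane–Anscombe 0.5 correction for the OR/CI (flagged); the p-value stays
  exact.
* **MOI stratification** (`moi_stratify()`): AD-vs-AR 2x2 per predictor;
  X-linked and unknown MOI are excluded, and degenerate strata are reported
  as not testable. Significance is read at two-sided alpha = 0.05 with no
  multiple-testing correction, matching the source analysis.
* **Summaries** (`build_summary()`): machine output keeps counts; the
  human-readable integer percentages round half away from zero.
* Both the median and the mean of concordance cells can be computed; the two
  are labelled distinctly because summaries of the same matrix have been
  reported under both names.

## The synthetic cohort generator

No clinical cohort ships with the package, so `generate_cohort()` provides
the statistical structure the pipeline assumes. Each variant draws a latent
state (pathogenic-like with probability `pi_path = 0.3`); evidence criteria
are emitted per-state with fixed Bernoulli probabilities, plus PP3 *or* BP4
(never both) at Supporting with probability `p_insilico = 0.52`; predictor
scores share one latent factor: `z = alpha_state + rho g + sqrt(1 - rho^2)
eps`, squashed through a logistic and placed in each predictor's range with
its orientation (so SIFT and ESM1b invert). Defaults were chosen once to land
in the observed cohort bands — a majority-VUS mix (the default preset
generates ~84% VUS), PP3 usage ~26% and BP4 ~25% (within the observed 19–44%
and 7–33% bands), `rho = 0.9` for strong inter-predictor agreement, and
dataset sizes at 1/10 of the published cohort (`preset = "small"`, 722
variants; `preset = "full"` for full scale). Streams are split per variant
from a counter, so enlarging the final dataset (or appending datasets) never
perturbs earlier variants.

What the generator does *not* emulate — and therefore what passing tests do
not show about clinical data: real gene coordinates and allele frequencies,
gene- or region-specific predictor behaviour (the kind of locus effects that
concentrate reclassifications in single genes), curator-specific evidence
usage, and the near-total inter-VEP concordance of the clinical tables (the
generator's concordance is lower because each predictor's calibration
geometry differs while its scores share only one latent factor).

`expected_change_fraction()` is the generator's companion oracle: it
re-implements score-interval lookup, evidence swap and rule combination
inline — independently of the pipeline code path — and recomputes the
eligible-VUS change fraction by straight per-variant simulation. Run on the
same seed it is an element-wise replay that must agree exactly; run on an
independent seed it must agree within binomial error. Both forms are tested.

## Numerical and scale choices

Interval boundaries compare with exact inequalities per the inclusivity
flags (no epsilon fuzzing); config validation tolerates only 1e-12 of slack
when checking interval adjacency. Undefined quantities (empty denominators,
empty medians) are `NA`, never 0 or 100. Routine test runs use cohorts of a
few hundred to 2000 variants and the 1/10-scale preset; an end-to-end
simulate → reclassify (8 predictors) → concord → summarize run at that scale
completes in a few seconds.

## Known limitations

* The shipped thresholds are a transcription; users applying the package to
  real data should verify them against the current ClinGen recommendations
  and supply their own YAML if they differ.
* The engine implements the generic 2015 rules, not gene-specific VCEP rule
  sets or the newer points-based framework.
* Only missense-style single-variant evidence profiles are modelled; no
  phenotype matching, segregation re-analysis or splice/noncoding predictors.
* The concordance of the synthetic cohort is not calibrated to the clinical
  tables (see above); synthetic results validate the machinery, not the
  clinical effect size.
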
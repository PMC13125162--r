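# vusreclass

Clinical laboratories classify missense variants under the ACMG/AMP 2015
framework by combining coded evidence criteria into one of five tiers
(Pathogenic, Likely pathogenic, VUS, Likely benign, Benign). Computational
predictions enter through two codes — PP3 (predicted deleterious) and BP4
(predicted benign) — originally capped at the weakest, Supporting, level.
ClinGen's recalibration of variant effect predictors (VEPs) showed that
specific score thresholds justify stronger evidence, up to
`PP3_Strong`/`BP4_VeryStrong`.

`vusreclass` is for analysts who want to measure what those calibrated
thresholds do to an existing curated cohort: it swaps the calibrated PP3/BP4
assignment into each variant's evidence profile (one predictor at a time,
replacing — never stacking — the legacy in-silico evidence), recombines under
the 2015 rules, and reports reclassification percentages, inter-predictor
concordance, Fisher-exact odds ratios and per-dataset summaries.

## The core machinery

* **Combining engine** — evidence profiles are multisets of criteria with
  effective strengths (`PM2`, `PP3_Strong`, ...). Counting is code-agnostic:
  a criterion raised to Strong fills a Strong slot exactly as PS1 would. The
  published pathogenic/likely-pathogenic/benign/likely-benign rule sets are
  applied; rules firing on both polarities conflict and yield VUS.
* **Calibration mapper** — per predictor, ordered score intervals map a raw
  score to `(PP3|BP4|NONE, strength)` with explicit orientation (SIFT and
  ESM1b are lower-is-deleterious) and boundary inclusivity. Eight predictors
  ship with transcribed ClinGen thresholds: REVEL, VARITY, AlphaMissense,
  ESM1b, BayesDel, VEST4, SIFT, PolyPhen-2.
* **Evidence swap** — per (variant, predictor):
  `new_class = combine(revise(baseline_profile, map(score)))`, restricted by
  default to variants whose baseline already used PP3/BP4.
* **Statistics** — pairwise concordance of VUS reclassifications (agreement
  on the destination tier among variants changed by either predictor),
  sample odds ratios with Woolf 95% CIs and exact Fisher p-values,
  AD-vs-AR stratification, Table-style per-dataset summaries.
* **Synthetic cohorts** — a seeded two-state latent model with one shared
  Gaussian score factor generates cohorts with the structure the analysis
  assumes, so the whole pipeline is testable without clinical data.

## Worked example

The package ships a six-variant hearing-loss fixture: the published variant
identities and predictor scores of the six VUS that reached Benign, with a
reconstructed `BS1,BP4` baseline profile (the `_synthetic` suffix marks that
assumption).

```r
library(vusreclass)
tab <- load_calibration()

map_score("VARITY", 0.021316, tab)
#>   assign strength
#> 1    BP4   STRONG

v <- read_variant_table(system.file("extdata",
       "hl_benign_reclass_variants_synthetic.tsv", package = "vusreclass"))
#> read_variant_table: 6 record(s) kept as reported (curated class differs from the engine)
s <- read_score_table(system.file("extdata",
       "hl_benign_reclass_scores.tsv", package = "vusreclass"))
v <- annotate_scores(v, s)
#> annotate_scores: per-predictor missing scores: REVEL=5, VARITY=1

out <- reclassify_cohort(v, "VARITY", tab)
subset(out, !score_missing,
       select = c(gene, score, assign, assigned_strength, old_class, new_class))
#>    gene    score assign assigned_strength old_class new_class
#> 2 USH2A 0.032904    BP4            STRONG       VUS         B
#> 3  WFS1 0.021316    BP4            STRONG       VUS         B
#> 4 GSDME 0.020728    BP4            STRONG       VUS         B
#> 5  CHD7 0.012199    BP4            STRONG       VUS         B
#> 6 MYH14 0.019462    BP4            STRONG       VUS         B
```

All five VARITY-scored variants earn `BP4_Strong`; with the baseline `BS1`
that makes two Strong benign criteria, so each VUS reaches Benign (the sixth
variant does the same through its REVEL score of 0.014). Cohort-level
association works from printed marginals alone:

```r
fisher_exact_or(matrix(c(604, 206, 5138, 1273), 2, byrow = TRUE))
#> OR 0.726 (95% CI 0.613-0.861), Fisher p = 0.000307
```

i.e. the genome-wide dataset is significantly less likely to report VUS than
the pooled gene panels (OR 0.73, 95% CI 0.61–0.86).

A command-line front end wraps the same functions:

```sh
exec/vusreclass simulate --seed 1 --out runs/sim
exec/vusreclass reclassify --variants runs/sim/variants.tsv \
    --scores runs/sim/scores.tsv --out runs/rc
exec/vusreclass concord --outcomes runs/rc/outcomes.tsv --out runs/cc
```

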
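# Evidence-swap reclassification: replace curated PP3/BP4 with the
# calibrated assignment for one predictor, recombine, record transitions.

#' Replace the in-silico evidence in a profile
#'
#' Removes any existing PP3 and BP4 entries and, when the calibrated
#' assignment is not `NONE`, inserts the assigned code at its calibrated
#' strength. All non-computational criteria are untouched, and PP3 and BP4 are
#' never simultaneously present afterwards.
#'
#' @param profile An [evidence_profile()].
#' @param assign `"PP3"`, `"BP4"` or `"NONE"`.
#' @param strength Strength token when `assign` is PP3/BP4.
#' @param retain_baseline_on_none If `TRUE`, an assignment of `NONE` keeps the
#'   baseline PP3/BP4 entry instead of dropping it (default `FALSE`: a
#'   calibrated score in the indeterminate region supplies no evidence).
#' @return The revised [evidence_profile()].
#' @export
#' @examples
#' revise_evidence(parse_evidence("PM1,PP3"), "PP3", "STRONG")
revise_evidence <- function(profile, assign, strength = NA_character_,
                            retain_baseline_on_none = FALSE) {
  stopifnot(inherits(profile, "evidence_profile"))
  assign <- toupper(assign)
  if (!assign %in% .assign_values) {
    stop("assignment must be PP3, BP4 or NONE, got: ", assign, call. = FALSE)
  }
  if (assign == "NONE" && retain_baseline_on_none) return(profile)
  codes <- names(profile)
  keep <- !codes %in% c("PP3", "BP4")
  codes <- codes[keep]
  strengths <- unname(unclass(profile))[keep]
  if (assign != "NONE") {
    if (is.na(strength)) {
      stop("a PP3/BP4 assignment requires a strength", call. = FALSE)
    }
    codes <- c(codes, assign)
    strengths <- c(strengths, strength)
  }
  evidence_profile(codes, strengths)
}

.eligibility_modes <- c("baseline-insilico", "all")

.has_insilico <- function(profile) any(names(profile) %in% c("PP3", "BP4"))

#' Reclassify a cohort of variants against one predictor
#'
#' For each variant: decide eligibility (`"baseline-insilico"` restricts the
#' analysis to variants whose curated baseline profile already applied PP3 or
#' BP4; `"all"` takes every variant), map the predictor score through the
#' calibration table, swap the resulting assignment into the baseline profile
#' with [revise_evidence()], and recombine under the 2015 rules. Ineligible
#' variants and variants without a score keep their baseline class; missing
#' scores are flagged so they can be excluded from denominators.
#'
#' @param variants Variant data.frame as returned by [read_variant_table()] or
#'   [generate_cohort()]: columns `chrom, pos, ref, alt, dataset, moi,
#'   baseline_class, evidence` plus a `score_<predictor>` column (see
#'   [annotate_scores()]).
#' @param predictor Predictor name present in `table`.
#' @param table A `calibration_table`.
#' @param mode Eligibility mode, `"baseline-insilico"` (default) or `"all"`.
#' @param options An [acmg_options()] list.
#' @param retain_baseline_on_none Passed to [revise_evidence()].
#' @return A data.frame of reclassification outcomes, one row per variant,
#'   with columns `chrom, pos, ref, alt, gene, dataset, moi, predictor, score,
#'   assign, assigned_strength, old_class, new_class, eligible, score_missing,
#'   changed`, and a `"transitions"` attribute holding the 5x5 transition
#'   matrix over eligible variants (see [transition_matrix()]).
#' @export
reclassify_cohort <- function(variants, predictor, table = load_calibration(),
                              mode = c("baseline-insilico", "all"),
                              options = acmg_options(),
                              retain_baseline_on_none = FALSE) {
  mode <- match.arg(mode)
  if (!predictor %in% names(table)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  score_col <- paste0("score_", predictor)
  if (!score_col %in% names(variants)) {
    stop("variants carry no score column for predictor ", predictor,
         " (expected column ", score_col, "); run annotate_scores() first",
         call. = FALSE)
  }
  n <- nrow(variants)
  old_class <- normalize_class(variants$baseline_class)
  scores <- as.numeric(variants[[score_col]])
  rng <- table[[predictor]]$range
  out_of_range <- !is.na(scores) & (scores < rng[1] | scores > rng[2])
  if (any(out_of_range)) {
    message("reclassify_cohort: ", sum(out_of_range), " score(s) outside ",
            predictor, "'s declared range; variant(s) skipped for this predictor")
    scores[out_of_range] <- NA_real_
  }
  mapped <- map_score(predictor, scores, table)
  assign <- rep(NA_character_, n)
  assigned_strength <- rep(NA_character_, n)
  new_class <- old_class
  eligible <- logical(n)
  score_missing <- is.na(scores)
  for (i in seq_len(n)) {
    prof <- parse_evidence(variants$evidence[i])
    eligible[i] <- mode == "all" || .has_insilico(prof)
    if (!eligible[i] || score_missing[i]) next
    assign[i] <- mapped$assign[i]
    assigned_strength[i] <- mapped$strength[i]
    revised <- revise_evidence(prof, mapped$assign[i], mapped$strength[i],
                               retain_baseline_on_none = retain_baseline_on_none)
    new_class[i] <- combine_evidence(revised, options)
  }
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene = if ("gene" %in% names(variants)) variants$gene else NA_character_,
    dataset = if ("dataset" %in% names(variants)) variants$dataset else NA_character_,
    moi = if ("moi" %in% names(variants)) variants$moi else NA_character_,
    predictor = predictor,
    score = scores,
    assign = assign,
    assigned_strength = assigned_strength,
    old_class = old_class,
    new_class = new_class,
    eligible = eligible,
    score_missing = score_missing,
    changed = eligible & !score_missing & old_class != new_class,
    stringsAsFactors = FALSE
  )
  attr(out, "transitions") <- transition_matrix(out)
  out
}

#' Transition matrix of reclassification outcomes
#'
#' Tallies eligible variants by (old tier, new tier); row sums over new tiers
#' therefore equal the number of eligible variants at each baseline tier.
#'
#' @param outcomes Outcome data.frame from [reclassify_cohort()].
#' @return A 5x5 integer matrix, rows = old tier, columns = new tier, in
#'   `classification_tiers()` order.
#' @export
transition_matrix <- function(outcomes) {
  tiers <- classification_tiers()
  el <- outcomes[outcomes$eligible, , drop = FALSE]
  table(factor(el$old_class, levels = tiers),
        factor(el$new_class, levels = tiers))
}

#' Reclassification percentage in a stratum
#'
#' 100 x changed / denominator, where the denominator is the eligible outcomes
#' with a present score in the requested stratum. The headline statistic uses
#' `old_class = "VUS"` (the default): the percentage of missense VUS whose
#' classification changed.
#'
#' @param outcomes Outcome data.frame from [reclassify_cohort()].
#' @param old_class Baseline tier filter (`NULL` for all tiers).
#' @param dataset,moi Optional stratum filters.
#' @return A percentage, or `NA_real_` when the denominator is zero.
#' @export
reclassification_percentage <- function(outcomes, old_class = "VUS",
                                        dataset = NULL, moi = NULL) {
  keep <- outcomes$eligible & !outcomes$score_missing
  if (!is.null(old_class)) keep <- keep & outcomes$old_class %in% old_class
  if (!is.null(dataset)) keep <- keep & outcomes$dataset %in% dataset
  if (!is.null(moi)) keep <- keep & outcomes$moi %in% moi
  denom <- sum(keep)
  if (denom == 0L) return(NA_real_)
  100 * sum(outcomes$changed[keep]) / denom
}

#' Ablate in-silico evidence from baseline classifications
#'
#' Estimates the contribution of the 2015-style PP3/BP4 usage by removing any
#' PP3/BP4 entry from each baseline profile and recombining; predictor scores
#' are ignored entirely. Every variant is eligible.
#'
#' @param variants Variant data.frame (columns as in [reclassify_cohort()]).
#' @param options An [acmg_options()] list.
#' @return An outcome data.frame in the [reclassify_cohort()] layout with
#'   `predictor = "ablation"`.
#' @export
ablate_insilico <- function(variants, options = acmg_options()) {
  n <- nrow(variants)
  old_class <- normalize_class(variants$baseline_class)
  new_class <- old_class
  for (i in seq_len(n)) {
    prof <- parse_evidence(variants$evidence[i])
    new_class[i] <- combine_evidence(
      revise_evidence(prof, "NONE"), options
    )
  }
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene = if ("gene" %in% names(variants)) variants$gene else NA_character_,
    dataset = if ("dataset" %in% names(variants)) variants$dataset else NA_character_,
    moi = if ("moi" %in% names(variants)) variants$moi else NA_character_,
    predictor = "ablation",
    score = NA_real_,
    assign = "NONE",
    assigned_strength = NA_character_,
    old_class = old_class,
    new_class = new_class,
    eligible = TRUE,
    score_missing = FALSE,
    changed = old_class != new_class,
    stringsAsFactors = FALSE
  )
  attr(out, "transitions") <- transition_matrix(out)
  out
}
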
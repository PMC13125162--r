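# Cohort-level summaries: VUS reclassification concordance between
# predictors, Fisher-exact odds ratios, MOI stratification, Table-1-style
# summaries.

# integer rounding, half away from zero (summary-table style)
.round_half_up <- function(x) trunc(x + sign(x) * 0.5)

.outcome_key <- function(outcomes) {
  paste(outcomes$chrom, outcomes$pos, outcomes$ref, outcomes$alt,
        outcomes$dataset, sep = ":")
}

#' Pairwise VUS-reclassification concordance between two predictors
#'
#' Restricted to baseline-VUS outcomes, the union set is the variants whose
#' classification changed under either predictor; the concordant set is the
#' variants changed by both predictors *to the same destination tier* (set
#' `destination_agnostic = TRUE` for the weaker "both changed" reading). The
#' reported percentage is 100 x concordant / union, undefined (`NA`) when the
#' union is empty.
#'
#' @param outcomes_a,outcomes_b Outcome data.frames from
#'   [reclassify_cohort()] covering the same cohort.
#' @param destination_agnostic Count agreement on change alone, ignoring the
#'   destination tier.
#' @return A one-row data.frame: `predictor_a, predictor_b, n_concordant,
#'   n_union, pct`.
#' @export
pairwise_concordance <- function(outcomes_a, outcomes_b,
                                 destination_agnostic = FALSE) {
  key_a <- .outcome_key(outcomes_a)
  key_b <- .outcome_key(outcomes_b)
  if (!setequal(key_a, key_b)) {
    stop("outcome sets do not cover the same cohort", call. = FALSE)
  }
  a <- outcomes_a[outcomes_a$old_class == "VUS" & outcomes_a$changed, , drop = FALSE]
  b <- outcomes_b[outcomes_b$old_class == "VUS" & outcomes_b$changed, , drop = FALSE]
  ka <- .outcome_key(a); kb <- .outcome_key(b)
  union_keys <- union(ka, kb)
  both <- intersect(ka, kb)
  if (destination_agnostic) {
    n_conc <- length(both)
  } else {
    dest_a <- a$new_class[match(both, ka)]
    dest_b <- b$new_class[match(both, kb)]
    n_conc <- sum(dest_a == dest_b)
  }
  n_union <- length(union_keys)
  data.frame(
    predictor_a = outcomes_a$predictor[1],
    predictor_b = outcomes_b$predictor[1],
    n_concordant = n_conc,
    n_union = n_union,
    pct = if (n_union > 0L) 100 * n_conc / n_union else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Inter-predictor concordance matrix
#'
#' One concordance cell per unordered predictor pair per dataset, plus
#' per-predictor and per-dataset medians over the defined cells and the count
#' of cells at exactly 100% concordance.
#'
#' @param outcomes Stacked outcome data.frame covering >= 2 predictors (rbind
#'   of [reclassify_cohort()] results on the same cohort).
#' @param destination_agnostic Passed to [pairwise_concordance()].
#' @return A list: `cells` (data.frame `dataset, predictor_a, predictor_b,
#'   n_concordant, n_union, pct`), `predictor_medians`, `dataset_medians`,
#'   `n_cells`, `n_full_concordance` (pct == 100), `n_undefined` (empty
#'   union).
#' @export
concordance_matrix <- function(outcomes, destination_agnostic = FALSE) {
  preds <- unique(outcomes$predictor)
  if (length(preds) < 2L) stop("need at least two predictors", call. = FALSE)
  datasets <- unique(outcomes$dataset)
  cells <- list()
  for (d in datasets) {
    od <- outcomes[outcomes$dataset == d, , drop = FALSE]
    for (i in seq_len(length(preds) - 1L)) {
      for (j in seq(i + 1L, length(preds))) {
        cell <- pairwise_concordance(
          od[od$predictor == preds[i], , drop = FALSE],
          od[od$predictor == preds[j], , drop = FALSE],
          destination_agnostic = destination_agnostic
        )
        cell <- cbind(dataset = d, cell, stringsAsFactors = FALSE)
        cells[[length(cells) + 1L]] <- cell
      }
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  pred_medians <- vapply(preds, function(p) {
    v <- cells$pct[cells$predictor_a == p | cells$predictor_b == p]
    stats::median(v[!is.na(v)])
  }, 0)
  ds_medians <- vapply(datasets, function(d) {
    v <- cells$pct[cells$dataset == d]
    stats::median(v[!is.na(v)])
  }, 0)
  list(
    cells = cells,
    predictor_medians = pred_medians,
    dataset_medians = ds_medians,
    n_cells = nrow(cells),
    n_full_concordance = sum(!is.na(cells$pct) & cells$pct == 100),
    n_undefined = sum(is.na(cells$pct))
  )
}

#' Fisher exact test with sample odds ratio and Woolf interval
#'
#' The p-value is the two-sided Fisher exact probability (the sum of
#' hypergeometric probabilities no larger than the observed table's, via
#' [stats::fisher.test()]). The reported point estimate is the *sample* odds
#' ratio ad/bc with a 95% Woolf (logit) interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)); the conditional-MLE
#' estimate from `fisher.test` is returned alongside. Tables with a zero cell
#' get the Haldane-Anscombe 0.5 correction for the OR and CI (flagged); the
#' p-value remains exact.
#'
#' @param table A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` in row-major order.
#' @param conf_level Confidence level for the Woolf interval.
#' @return A list of class `odds_ratio_result`: `table`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `or_cmle`, `corrected`.
#' @export
#' @examples
#' fisher_exact_or(matrix(c(604, 206, 5138, 1273), 2, byrow = TRUE))
fisher_exact_or <- function(table, conf_level = 0.95) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  stopifnot(all(dim(table) == 2L), all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("both margins of the 2x2 table must be positive", call. = FALSE)
  }
  ft <- stats::fisher.test(table)
  corrected <- any(table == 0)
  w <- if (corrected) table + 0.5 else table
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    table = table,
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_value = ft$p.value,
    or_cmle = unname(ft$estimate),
    corrected = corrected
  ), class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), Fisher p = %.3g%s\n",
              x$or, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Odds of reporting VUS in one dataset versus pooled comparison datasets
#'
#' Builds the 2x2 table (focal VUS, focal non-VUS; pooled VUS, pooled
#' non-VUS) from a [build_summary()] table and delegates to
#' [fisher_exact_or()].
#'
#' @param summary A [build_summary()] data.frame.
#' @param focal Focal dataset label.
#' @param comparison Comparison dataset labels (default: all others).
#' @return An `odds_ratio_result`.
#' @export
vus_likelihood_or <- function(summary, focal,
                              comparison = setdiff(summary$dataset, focal)) {
  stopifnot(focal %in% summary$dataset, !focal %in% comparison,
            length(comparison) >= 1L, all(comparison %in% summary$dataset))
  f <- summary[summary$dataset == focal, ]
  cmp <- summary[summary$dataset %in% comparison, ]
  tab <- matrix(c(f$n_VUS, f$n - f$n_VUS,
                  sum(cmp$n_VUS), sum(cmp$n) - sum(cmp$n_VUS)),
                2L, 2L, byrow = TRUE)
  fisher_exact_or(tab)
}

#' Median of a group of percentages
#'
#' Standard median (mean of the central pair for even counts) after removing
#' undefined entries; `NA` for an empty group.
#'
#' @param x Numeric vector (NAs are dropped).
#' @return The median, or `NA_real_` when nothing remains.
#' @export
median_reclassification <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  stats::median(x)
}

#' MOI-stratified reclassification comparison per predictor
#'
#' For each predictor, tallies changed/unchanged eligible baseline-VUS
#' outcomes with present scores in the autosomal dominant and autosomal
#' recessive strata (X-linked and unknown MOI are excluded) and runs
#' [fisher_exact_or()] on the 2x2 table (AD changed, AD unchanged; AR changed,
#' AR unchanged). Predictors with an empty stratum or an empty table margin
#' are reported as not testable.
#'
#' @param outcomes Stacked outcome data.frame (>= 1 predictor).
#' @return A data.frame with one row per predictor: stratum counts, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `testable`.
#' @export
moi_stratify <- function(outcomes) {
  preds <- unique(outcomes$predictor)
  rows <- lapply(preds, function(p) {
    o <- outcomes[outcomes$predictor == p & outcomes$eligible &
                    !outcomes$score_missing & outcomes$old_class == "VUS", ]
    ad <- o[o$moi == "AD", ]; ar <- o[o$moi == "AR", ]
    row <- data.frame(
      predictor = p,
      ad_changed = sum(ad$changed), ad_unchanged = sum(!ad$changed),
      ar_changed = sum(ar$changed), ar_unchanged = sum(!ar$changed),
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, testable = FALSE,
      stringsAsFactors = FALSE
    )
    tab <- matrix(c(row$ad_changed, row$ad_unchanged,
                    row$ar_changed, row$ar_unchanged), 2L, 2L, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      fr <- fisher_exact_or(tab)
      row$or <- fr$or; row$ci_low <- fr$ci_low; row$ci_high <- fr$ci_high
      row$p_value <- fr$p_value; row$testable <- TRUE
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-dataset cohort summary
#'
#' The Table-1-style summary: per dataset, the number of unique variants and
#' genes, counts and integer percentages per classification tier, and counts
#' and percentages of baseline profiles applying PP3 and BP4. Percentages are
#' rounded half away from zero, matching the human-readable style; use the
#' counts for machine consumption.
#'
#' @param variants Variant data.frame with columns `dataset, gene,
#'   baseline_class, evidence`.
#' @return A data.frame with one row per dataset: `dataset, n, n_genes,
#'   n_B ... n_P, pct_B ... pct_P, n_PP3, pct_PP3, n_BP4, pct_BP4`.
#' @export
build_summary <- function(variants) {
  datasets <- unique(variants$dataset)
  cls <- normalize_class(variants$baseline_class)
  has <- vapply(variants$evidence, function(e) {
    codes <- names(parse_evidence(e))
    c(PP3 = "PP3" %in% codes, BP4 = "BP4" %in% codes)
  }, logical(2))
  rows <- lapply(datasets, function(d) {
    idx <- variants$dataset == d
    n <- sum(idx)
    counts <- vapply(classification_tiers(), function(t) sum(cls[idx] == t), 0L)
    row <- data.frame(dataset = d, n = n,
                      n_genes = length(unique(variants$gene[idx])),
                      stringsAsFactors = FALSE)
    for (t in classification_tiers()) row[[paste0("n_", t)]] <- counts[[t]]
    for (t in classification_tiers()) {
      row[[paste0("pct_", t)]] <-
        if (n > 0) .round_half_up(100 * counts[[t]] / n) else 0
    }
    row$n_PP3 <- sum(has["PP3", idx]); row$n_BP4 <- sum(has["BP4", idx])
    row$pct_PP3 <- if (n > 0) .round_half_up(100 * row$n_PP3 / n) else 0
    row$pct_BP4 <- if (n > 0) .round_half_up(100 * row$n_BP4 / n) else 0
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stacked-bar report of VUS reclassification destinations
#'
#' Per predictor and dataset, the percentage of eligible baseline-VUS
#' outcomes reclassified to LP (dark) and LB (light), as a ggplot2 stacked
#' bar chart. Requires ggplot2.
#'
#' @param outcomes Stacked outcome data.frame.
#' @return A ggplot object.
#' @export
plot_reclassification <- function(outcomes) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_reclassification() requires the ggplot2 package", call. = FALSE)
  }
  o <- outcomes[outcomes$eligible & !outcomes$score_missing &
                  outcomes$old_class == "VUS", ]
  combos <- unique(o[, c("predictor", "dataset")])
  rows <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    oi <- o[o$predictor == combos$predictor[i] & o$dataset == combos$dataset[i], ]
    data.frame(
      predictor = combos$predictor[i], dataset = combos$dataset[i],
      destination = c("LP", "LB"),
      pct = 100 * c(sum(oi$new_class == "LP"), sum(oi$new_class == "LB")) /
        max(1L, nrow(oi)),
      stringsAsFactors = FALSE
    )
  }))
  ggplot2::ggplot(rows, ggplot2::aes(
    x = predictor, y = pct, fill = destination)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::scale_fill_manual(values = c(LP = "grey20", LB = "grey70")) +
    ggplot2::labs(x = NULL, y = "% of eligible VUS reclassified",
                  fill = "New tier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
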
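# Concordance, odds ratios, medians, summaries.

make_outcomes <- function(n, changed_idx, new_class = "LB",
                          predictor = "A", dataset = "GWS") {
  o <- data.frame(
    chrom = "1", pos = seq_len(n), ref = "A", alt = "C", gene = "G",
    dataset = dataset, moi = "AD", predictor = predictor, score = 0.5,
    assign = "NONE", assigned_strength = NA_character_,
    old_class = "VUS", new_class = "VUS",
    eligible = TRUE, score_missing = FALSE, changed = FALSE,
    stringsAsFactors = FALSE
  )
  o$changed[changed_idx] <- TRUE
  o$new_class[changed_idx] <- rep_len(new_class, length(changed_idx))
  o
}

test_that("pairwise concordance counts union and same-destination overlap", {
  a <- make_outcomes(50, 1:10, "LB", predictor = "A")
  b <- make_outcomes(50, 1:10, "LB", predictor = "B")
  cell <- pairwise_concordance(a, b)
  expect_equal(cell$pct, 100)
  expect_equal(cell$n_union, 10)
  # disjoint changed sets
  cell <- pairwise_concordance(a, make_outcomes(50, 11:20, "LB", predictor = "B"))
  expect_equal(cell$pct, 0)
  # same variants, different destinations: discordant unless destination-agnostic
  b2 <- make_outcomes(50, 1:10, "LP", predictor = "B")
  expect_equal(pairwise_concordance(a, b2)$pct, 0)
  expect_equal(pairwise_concordance(a, b2, destination_agnostic = TRUE)$pct, 100)
  # symmetry
  b3 <- make_outcomes(50, 6:15, "LB", predictor = "B")
  expect_equal(pairwise_concordance(a, b3)$pct, pairwise_concordance(b3, a)$pct)
  expect_equal(pairwise_concordance(a, b3)$n_union, 15)
  expect_equal(pairwise_concordance(a, b3)$n_concordant, 5)
  # empty union is undefined, not 100
  none_a <- make_outcomes(50, integer(0), predictor = "A")
  none_b <- make_outcomes(50, integer(0), predictor = "B")
  expect_true(is.na(pairwise_concordance(none_a, none_b)$pct))
  # mismatched cohorts rejected
  expect_error(pairwise_concordance(a, make_outcomes(40, 1:5, predictor = "B")),
               "cohort")
})

test_that("concordance matrix produces one cell per pair per dataset", {
  sets <- do.call(rbind, lapply(c("A", "B"), function(p)
    make_outcomes(30, 1:5, "LB", predictor = p, dataset = "GWS")))
  cm <- concordance_matrix(sets)
  expect_equal(cm$n_cells, 1)
  expect_equal(cm$n_full_concordance, 1)
  expect_equal(unname(cm$predictor_medians["A"]), 100)
  expect_error(concordance_matrix(make_outcomes(10, 1:2)), "two predictors")
})

test_that("median helper matches hand-computed medians", {
  expect_equal(median_reclassification(c(3, 5, 7)), 5)
  expect_equal(median_reclassification(c(90.68, 100)), 95.34)
  expect_equal(median_reclassification(c(100, 90, 80)), 90)
  expect_equal(median_reclassification(c(NA, 4, NA, 6)), 5)
  expect_true(is.na(median_reclassification(numeric(0))))
  set.seed(1)
  x <- runif(9, 0, 100)
  expect_equal(median_reclassification(sample(x)), median_reclassification(x))
  expect_gte(median_reclassification(x), min(x))
  expect_lte(median_reclassification(x), max(x))
})

test_that("fisher_exact_or reports the sample OR with a Woolf interval", {
  r <- fisher_exact_or(matrix(c(604, 206, 5138, 1273), 2, byrow = TRUE))
  expect_equal(round(r$or, 2), 0.73)
  expect_equal(round(r$ci_low, 2), 0.61)
  expect_equal(round(r$ci_high, 2), 0.86)
  expect_false(r$corrected)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
  # proportional table has OR exactly 1
  expect_equal(fisher_exact_or(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))$or, 1)
  # Haldane-Anscombe correction on a zero cell: (1.5*1.5)/(0.5*0.5) = 9
  r0 <- fisher_exact_or(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_true(r0$corrected)
  expect_equal(r0$or, 9)
  expect_error(fisher_exact_or(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("fisher p-values equal direct hypergeometric enumeration", {
  set.seed(11)
  for (rep in 1:40) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_or(tab)$p_value, fisher_p_hyper(tab),
                 tolerance = 1e-10,
                 label = paste(tab, collapse = ","))
  }
})

test_that("vus_likelihood_or pools comparison datasets order-invariantly", {
  smry <- data.frame(
    dataset = c("GWS", "P1", "P2", "P3"),
    n = c(800, 500, 400, 300),
    n_VUS = c(600, 400, 350, 250)
  )
  r1 <- vus_likelihood_or(smry, "GWS", c("P1", "P2", "P3"))
  r2 <- vus_likelihood_or(smry, "GWS", c("P3", "P1", "P2"))
  expect_equal(r1$or, r2$or)
  expect_equal(r1$p_value, r2$p_value)
  # identical VUS fraction gives OR 1
  smry2 <- data.frame(dataset = c("A", "B"), n = c(100, 200), n_VUS = c(50, 100))
  expect_equal(vus_likelihood_or(smry2, "A")$or, 1)
  expect_error(vus_likelihood_or(smry, "GWS", character(0)))
})

test_that("MOI stratification builds the AD/AR table and flags untestable strata", {
  o_ad <- make_outcomes(100, 1:10, "LP", predictor = "X")
  o_ad$moi <- "AD"
  o_ar <- make_outcomes(100, 1:5, "LP", predictor = "X")
  o_ar$moi <- "AR"
  o_ar$pos <- o_ar$pos + 1000
  m <- moi_stratify(rbind(o_ad, o_ar))
  expect_true(m$testable)
  expect_equal(m$ad_changed, 10)
  expect_equal(m$ar_unchanged, 95)
  expect_equal(round(m$or, 2), round((10 * 95) / (90 * 5), 2))  # ~2.11
  # equal change rates: OR exactly 1
  m2 <- moi_stratify(rbind(o_ad, {
    x <- make_outcomes(100, 1:10, "LP", predictor = "X")
    x$moi <- "AR"; x$pos <- x$pos + 1000; x
  }))
  expect_equal(m2$or, 1)
  # empty AR stratum is not testable
  m3 <- moi_stratify(o_ad)
  expect_false(m3$testable)
  expect_true(is.na(m3$or))
})

test_that("the cohort summary counts tiers, genes and in-silico usage per dataset", {
  v <- make_variants(
    evidence = c("PP3,PM2", "BP4", "BS1,BP1", "PVS1,PS1", ""),
    baseline_class = c("VUS", "VUS", "LB", "P", "VUS")
  )
  v$dataset <- c("GWS", "GWS", "GWS", "GWS", "HL")
  v$gene <- c("G1", "G1", "G2", "G3", "G4")
  s <- build_summary(v)
  gws <- s[s$dataset == "GWS", ]
  expect_equal(gws$n, 4)
  expect_equal(gws$n_genes, 3)
  expect_equal(gws$n_VUS, 2)
  expect_equal(gws$pct_VUS, 50)
  expect_equal(gws$n_PP3, 1)
  expect_equal(gws$n_BP4, 1)
  expect_equal(gws$pct_PP3, 25)
  hl <- s[s$dataset == "HL", ]
  expect_equal(hl$n, 1)
  expect_equal(hl$n_VUS, 1)
  # integer percentages round half away from zero
  v2 <- make_variants(rep("", 8), baseline_class = c(rep("VUS", 3), rep("P", 5)))
  s2 <- build_summary(v2)
  expect_equal(s2$pct_VUS, 38)  # 37.5 rounds up
})
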
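# Independent oracles used across the suite.

# Literal transcription of the 2015 combining-rule table, written as an
# explicit rule list over per-level counts. Kept structurally separate from
# the package's classifier on purpose: it is the reference the engine is
# checked against.
oracle_classify <- function(codes, strengths,
                            single_bs_is_lb = TRUE, ba1_overrides = TRUE) {
  lvl <- c(SUPPORTING = 1, MODERATE = 2, STRONG = 3, VERY_STRONG = 4,
           STAND_ALONE = 5)
  r <- lvl[strengths]
  on_path_side <- substring(codes, 1, 1) == "P"
  PVS <- sum(r[on_path_side] == 4); PS <- sum(r[on_path_side] == 3)
  PM <- sum(r[on_path_side] == 2); PP <- sum(r[on_path_side] == 1)
  BA <- sum(r[!on_path_side] == 5)
  BS <- sum(r[!on_path_side] == 3) + BA
  # a Moderate benign item satisfies a Supporting-benign requirement
  BPs <- sum(r[!on_path_side] <= 2)

  pathogenic_rules <- list(
    function() PVS >= 1 && PS >= 1,          # (ia)
    function() PVS >= 1 && PM >= 2,          # (ib)
    function() PVS >= 1 && PM >= 1 && PP >= 1,  # (ic)
    function() PVS >= 1 && PP >= 2,          # (id)
    function() PVS >= 2,                     # two very-strong items
    function() PS >= 2,                      # (ii)
    function() PS >= 1 && PM >= 3,           # (iiia)
    function() PS >= 1 && PM >= 2 && PP >= 2,   # (iiib)
    function() PS >= 1 && PM >= 1 && PP >= 4    # (iiic)
  )
  likely_path_rules <- list(
    function() PVS >= 1 && PM >= 1,          # (i)
    function() PS >= 1 && PM >= 1,           # (ii)
    function() PS >= 1 && PP >= 2,           # (iii)
    function() PM >= 3,                      # (iv)
    function() PM >= 2 && PP >= 2,           # (v)
    function() PM >= 1 && PP >= 4            # (vi)
  )
  benign_rules <- list(
    function() BA >= 1,                      # stand-alone
    function() BS >= 2                       # >= 2 strong benign
  )
  likely_benign_rules <- list(
    function() BS >= 1 && BPs >= 1,          # (i)
    function() BPs >= 2,                     # (ii)
    function() single_bs_is_lb && BS >= 1 && !any(on_path_side)
  )
  fired <- function(rules) any(vapply(rules, function(f) f(), NA))
  p_fired <- fired(pathogenic_rules) || fired(likely_path_rules)
  b_fired <- fired(benign_rules) || fired(likely_benign_rules)
  if (BA >= 1 && ba1_overrides) return("B")
  if (p_fired && b_fired) return("VUS")
  if (fired(pathogenic_rules)) return("P")
  if (fired(likely_path_rules)) return("LP")
  if (fired(benign_rules)) return("B")
  if (fired(likely_benign_rules)) return("LB")
  "VUS"
}

# Two-sided Fisher exact p-value by direct hypergeometric enumeration:
# sum of P(X = x) over all x with P(X = x) <= P(observed), X ~ Hypergeom.
fisher_p_hyper <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# enumerate all per-polarity strength multisets with at most max_items items
# over the four orderable strengths (data.frame of counts)
strength_count_grid <- function(max_items) {
  g <- expand.grid(SUPPORTING = 0:max_items, MODERATE = 0:max_items,
                   STRONG = 0:max_items, VERY_STRONG = 0:max_items)
  g[rowSums(g) <= max_items, , drop = FALSE]
}

# turn per-polarity strength counts into a concrete evidence profile
profile_from_counts <- function(p_counts, b_counts) {
  p_pool <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
  b_pool <- c(paste0("BS", 1:4), paste0("BP", 1:7))
  p_str <- rep(names(p_counts), unlist(p_counts))
  b_str <- rep(names(b_counts), unlist(b_counts))
  evidence_profile(c(p_pool[seq_along(p_str)], b_pool[seq_along(b_str)]),
                   c(p_str, b_str))
}

# minimal variant table constructor for pipeline tests
make_variants <- function(evidence, baseline_class = NULL, score = NULL,
                          dataset = "GWS", moi = "AD", predictor = "REVEL") {
  n <- length(evidence)
  if (is.null(baseline_class)) {
    baseline_class <- vapply(evidence, function(e)
      combine_evidence(parse_evidence(e)), "", USE.NAMES = FALSE)
  }
  df <- data.frame(
    chrom = "1", pos = seq_len(n), ref = "A", alt = "C",
    gene = paste0("G", seq_len(n)), hgnc = NA_character_,
    transcript = NA_character_, hgvs_c = NA_character_,
    dataset = rep_len(dataset, n), moi = rep_len(moi, n),
    baseline_class = baseline_class, evidence = evidence,
    stringsAsFactors = FALSE
  )
  if (!is.null(score)) df[[paste0("score_", predictor)]] <- score
  df
}

# write a one-off calibration YAML and load it
make_calibration <- function(predictors) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(predictors = predictors), path)
  load_calibration(path)
}

# a simple synthetic single-predictor calibration spec
flat_none_spec <- function(range = c(0, 1)) {
  list(orientation = "higher_is_deleterious", range = range,
       intervals = list(list(lo = range[1], lo_incl = TRUE, hi = range[2],
                             hi_incl = TRUE, assign = "NONE")))
}
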
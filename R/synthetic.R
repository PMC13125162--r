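# Synthetic cohort generator: two-state latent pathogenicity model with a
# shared Gaussian factor driving correlated predictor scores, plus an
# emission model for baseline ACMG evidence profiles. Emulates the cohort
# structure the pipeline assumes (majority-VUS mix, partial PP3/BP4 usage,
# per-dataset gene panels, AD/AR/XL labels) without clinical data.

.table1_n <- c(GWS = 810, RD = 542, HL = 2472, AI = 717, CT = 1563,
               NS = 397, HSP = 720)
.table1_genes <- c(GWS = 550, RD = 41, HL = 67, AI = 35, CT = 79,
                   NS = 15, HSP = 40)

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study conditions the pipeline targets: seven
#' datasets (one genome-wide, six panels) in the published size proportions
#' (the `"small"` preset is 1/10 scale for fast tests, `"full"` is full
#' scale), a latent pathogenic fraction and evidence-emission probabilities
#' producing a majority-VUS classification mix, in-silico (PP3/BP4) usage
#' within the observed 20-60% band, and predictor scores driven by a shared
#' latent factor (loading `rho`) so predictors agree strongly on the same
#' variants.
#'
#' @param preset `"small"` (1/10 scale, default) or `"full"`.
#' @param n Named integer vector of variants per dataset (overrides preset).
#' @param gene_pool Named integer vector of gene-pool sizes per dataset.
#' @param moi_mix Named proportions for AD/AR/XL mode-of-inheritance labels.
#' @param pi_path Latent pathogenic-like fraction in `[0, 1]`.
#' @param p_insilico Probability a baseline profile applies PP3 or BP4.
#' @param p_pp3_given_path,p_pp3_given_benign Probability the applied
#'   in-silico code is PP3 (vs BP4), by latent state; PP3 and BP4 are never
#'   emitted together.
#' @param emissions List with elements `path` and `benign`: named per-code
#'   Bernoulli emission probabilities by latent state. May not contain
#'   PP3/BP4 (those come from the in-silico arm).
#' @param alpha Named vector `c(path =, benign =)` of latent score locations.
#' @param rho Shared-factor loading in `[0, 1)`.
#' @param seed Integer seed; the generator splits one deterministic stream per
#'   variant (counter-based), so extending a cohort never perturbs earlier
#'   variants.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("small", "full"),
                          n = NULL,
                          gene_pool = .table1_genes,
                          moi_mix = c(AD = 0.50, AR = 0.45, XL = 0.05),
                          pi_path = 0.30,
                          p_insilico = 0.52,
                          p_pp3_given_path = 0.85,
                          p_pp3_given_benign = 0.35,
                          emissions = list(
                            path = c(PM2 = 0.85, PM1 = 0.15, PM5 = 0.08,
                                     PS4 = 0.06, PS3 = 0.05, PVS1 = 0.04,
                                     PP1 = 0.25, PP2 = 0.20),
                            benign = c(BS1 = 0.10, BS2 = 0.04, BP1 = 0.12,
                                       BP7 = 0.05, PM2 = 0.25, PP2 = 0.05)
                          ),
                          alpha = c(path = 1.0, benign = -1.0),
                          rho = 0.9,
                          seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n)) {
    n <- if (preset == "small") pmax(round(.table1_n / 10), 1L) else .table1_n
  }
  probs <- c(moi_mix, pi_path, p_insilico, p_pp3_given_path, p_pp3_given_benign,
             unlist(emissions))
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (abs(sum(moi_mix) - 1) > 1e-8) stop("moi_mix must sum to 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  em_codes <- unlist(lapply(emissions, names))
  if (any(em_codes %in% c("PP3", "BP4"))) {
    stop("emission model may not emit PP3/BP4 directly (in-silico arm handles them)",
         call. = FALSE)
  }
  .check_codes(unique(em_codes))
  if (is.null(names(n)) || !all(names(n) %in% names(gene_pool))) {
    stop("every dataset in n needs a gene_pool entry", call. = FALSE)
  }
  structure(list(
    n = n, gene_pool = gene_pool, moi_mix = moi_mix, pi_path = pi_path,
    p_insilico = p_insilico, p_pp3_given_path = p_pp3_given_path,
    p_pp3_given_benign = p_pp3_given_benign, emissions = emissions,
    alpha = alpha, rho = rho, seed = as.integer(seed)
  ), class = "cohort_config")
}

# counter-based per-variant seed: extending the cohort never perturbs
# earlier variants' draws
.variant_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 100003) %%
               2147483629)
}

.squash_to_range <- function(u, range, orientation) {
  if (orientation == "HIGHER_IS_DELETERIOUS") {
    range[1] + u * (range[2] - range[1])
  } else {
    range[2] - u * (range[2] - range[1])
  }
}

#' Generate a synthetic variant cohort
#'
#' Deterministic given the config seed. Each variant receives a unique
#' synthetic key, a dataset label, a gene from the dataset's pool, an MOI
#' label, a baseline evidence profile sampled from the emission model (plus
#' possibly PP3 or BP4 at Supporting), the engine classification of that
#' profile, and one score per predictor: on the latent scale
#' `z = alpha_state + rho g + sqrt(1 - rho^2) eps`, squashed through the
#' logistic function and placed in the predictor's score range respecting its
#' orientation (so SIFT's scale is inverted). The hidden truth table
#' (latent state and shared factor) is returned separately for validation
#' only and is not a pipeline input.
#'
#' @param config A [cohort_config()].
#' @param table A `calibration_table` supplying predictor names, ranges and
#'   orientations.
#' @return A list: `variants` (variant table with `score_<predictor>` columns
#'   attached), `scores` (the standalone score table), `truth` (variant key,
#'   latent state, shared factor).
#' @export
generate_cohort <- function(config, table = load_calibration()) {
  stopifnot(inherits(config, "cohort_config"))
  preds <- names(table)
  datasets <- names(config$n)
  total <- sum(config$n)
  rows <- vector("list", total)
  score_mat <- matrix(NA_real_, nrow = total, ncol = length(preds),
                      dimnames = list(NULL, preds))
  truth_state <- character(total)
  truth_g <- numeric(total)
  counter <- 0L
  for (d in datasets) {
    for (i in seq_len(config$n[[d]])) {
      counter <- counter + 1L
      set.seed(.variant_seed(config$seed, counter))
      path_like <- stats::runif(1) < config$pi_path
      g <- stats::rnorm(1)
      moi <- sample(names(config$moi_mix), 1L, prob = config$moi_mix)
      gene_idx <- sample.int(config$gene_pool[[d]], 1L)
      em <- config$emissions[[if (path_like) "path" else "benign"]]
      emitted <- names(em)[stats::runif(length(em)) < em]
      use_insilico <- stats::runif(1) < config$p_insilico
      p_pp3 <- if (path_like) config$p_pp3_given_path else config$p_pp3_given_benign
      insilico_code <- if (stats::runif(1) < p_pp3) "PP3" else "BP4"
      if (use_insilico) emitted <- c(emitted, insilico_code)
      eps <- stats::rnorm(length(preds))
      z <- config$alpha[[if (path_like) "path" else "benign"]] +
        config$rho * g + sqrt(1 - config$rho^2) * eps
      u <- stats::plogis(z)
      for (k in seq_along(preds)) {
        score_mat[counter, k] <- .squash_to_range(
          u[k], table[[preds[k]]]$range, table[[preds[k]]]$orientation)
      }
      prof <- evidence_profile(emitted)
      rows[[counter]] <- data.frame(
        chrom = "1", pos = counter, ref = "A", alt = "C",
        gene = sprintf("%s_G%03d", d, gene_idx),
        hgnc = sprintf("HGNC:%d", 100000L + counter),
        transcript = "NM_000000.0",
        hgvs_c = sprintf("c.%dA>C", counter),
        dataset = d, moi = moi,
        baseline_class = combine_evidence(prof),
        evidence = format_evidence(prof),
        as_reported = FALSE,
        stringsAsFactors = FALSE
      )
      truth_state[counter] <- if (path_like) "PATHOGENIC_LIKE" else "BENIGN_LIKE"
      truth_g[counter] <- g
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  scores <- cbind(variants[, c("chrom", "pos", "ref", "alt")],
                  as.data.frame(score_mat))
  for (p in preds) variants[[paste0("score_", p)]] <- score_mat[, p]
  truth <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, true_state = truth_state, g = truth_g,
    stringsAsFactors = FALSE
  )
  list(variants = variants, scores = scores, truth = truth)
}

#' Independent Monte-Carlo oracle for the eligible-VUS change fraction
#'
#' Estimates the fraction of eligible baseline-VUS variants whose
#' classification changes for one predictor, by straight per-variant
#' simulation that re-implements the map -> revise -> combine chain inline,
#' without calling the pipeline code path ([map_score()],
#' [revise_evidence()], [reclassify_cohort()] or [combine_evidence()]).
#' Used to validate [reclassify_cohort()] within binomial error.
#'
#' @param config A [cohort_config()]; its dataset mix is kept, its total size
#'   is rescaled to `n_mc`.
#' @param table A `calibration_table`.
#' @param n_mc Number of simulated variants (>= 1).
#' @param seed Seed for the simulation stream.
#' @param predictor Predictor evaluated.
#' @param single_bs_is_lb Mirror of the engine flag.
#' @return The Monte-Carlo change fraction (`NA` if no variant was eligible),
#'   with attributes `n_eligible` and `n_changed`.
#' @export
expected_change_fraction <- function(config, table = load_calibration(),
                                     n_mc = 2000L, seed = 1L,
                                     predictor = "REVEL",
                                     single_bs_is_lb = TRUE) {
  stopifnot(n_mc >= 1L, predictor %in% names(table))
  cfg <- config
  cfg$n <- pmax(round(config$n * n_mc / sum(config$n)), 1L)
  cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cfg, table)
  v <- cohort$variants
  entry <- table[[predictor]]
  iv <- entry$intervals
  scores <- v[[paste0("score_", predictor)]]

  # inline strength bookkeeping, independent of the engine's parser
  base_strength <- function(code) {
    if (grepl("^PVS", code)) return(4L)
    if (grepl("^PS", code) || grepl("^BS", code)) return(3L)
    if (grepl("^PM", code)) return(2L)
    if (code == "BA1") return(5L)
    1L  # PP / BP
  }
  suffix_strength <- c(supporting = 1L, moderate = 2L, strong = 3L,
                       verystrong = 4L, standalone = 5L)
  token_strength <- function(token) {
    if (!grepl("_", token, fixed = TRUE)) {
      return(base_strength(token))
    }
    sfx <- gsub("[^a-z]", "", tolower(sub("^[^_]*_", "", token)))
    suffix_strength[[sfx]]
  }

  # inline transcription of the 2015 combining rules (second implementation)
  classify_inline <- function(tokens) {
    if (!length(tokens)) return("VUS")
    codes <- sub("_.*$", "", tokens)
    ranks <- vapply(tokens, token_strength, 0L)
    is_path <- startsWith(codes, "P")
    p <- ranks[is_path]; b <- ranks[!is_path]
    vs <- sum(p == 4L); st <- sum(p == 3L); mo <- sum(p == 2L); su <- sum(p == 1L)
    ba <- sum(b == 5L); bst <- sum(b == 3L) + ba; bsu <- sum(b <= 2L)
    patho <- FALSE
    if (vs >= 1 && (st >= 1 || mo >= 2 || (mo == 1 && su >= 1) || su >= 2)) patho <- TRUE
    if (vs >= 2) patho <- TRUE
    if (st >= 2) patho <- TRUE
    if (st >= 1 && mo >= 3) patho <- TRUE
    if (st >= 1 && mo == 2 && su >= 2) patho <- TRUE
    if (st >= 1 && mo == 1 && su >= 4) patho <- TRUE
    likely_patho <- FALSE
    if (vs >= 1 && mo >= 1) likely_patho <- TRUE
    if (st >= 1 && (mo >= 1 || su >= 2)) likely_patho <- TRUE
    if (mo >= 3) likely_patho <- TRUE
    if (mo == 2 && su >= 2) likely_patho <- TRUE
    if (mo == 1 && su >= 4) likely_patho <- TRUE
    benign <- ba >= 1 || bst >= 2
    likely_benign <- (bst >= 1 && bsu >= 1) || bsu >= 2 ||
      (single_bs_is_lb && bst >= 1 && !any(is_path))
    if (ba >= 1) return("B")
    if ((patho || likely_patho) && (benign || likely_benign)) return("VUS")
    if (patho) return("P")
    if (likely_patho) return("LP")
    if (benign) return("B")
    if (likely_benign) return("LB")
    "VUS"
  }

  n_eligible <- 0L
  n_changed <- 0L
  for (i in seq_len(nrow(v))) {
    tokens <- strsplit(v$evidence[i], ",", fixed = TRUE)[[1]]
    tokens <- tokens[nzchar(tokens)]
    codes <- sub("_.*$", "", tokens)
    if (v$baseline_class[i] != "VUS") next
    if (!any(codes %in% c("PP3", "BP4"))) next
    s <- scores[i]
    if (is.na(s)) next
    n_eligible <- n_eligible + 1L
    hit_assign <- "NONE"; hit_strength <- NA_character_
    for (r in seq_len(nrow(iv))) {
      above <- if (iv$lo_incl[r]) s >= iv$lo[r] else s > iv$lo[r]
      below <- if (iv$hi_incl[r]) s <= iv$hi[r] else s < iv$hi[r]
      if (above && below) {
        hit_assign <- iv$assign[r]
        hit_strength <- iv$strength[r]
        break
      }
    }
    revised <- tokens[!codes %in% c("PP3", "BP4")]
    if (hit_assign != "NONE") {
      revised <- c(revised,
                   paste0(hit_assign, "_", gsub("_", "", hit_strength)))
    }
    if (classify_inline(revised) != "VUS") n_changed <- n_changed + 1L
  }
  frac <- if (n_eligible > 0L) n_changed / n_eligible else NA_real_
  structure(frac, n_eligible = n_eligible, n_changed = n_changed)
}
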
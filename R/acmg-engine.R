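# ACMG/AMP 2015 evidence model: criterion catalogue, strength-modified evidence
# profiles, and the published combining rules.

.strength_levels <- c("SUPPORTING", "MODERATE", "STRONG", "VERY_STRONG", "STAND_ALONE")

.strength_suffixes <- c(
  SUPPORTING = "Supporting", MODERATE = "Moderate", STRONG = "Strong",
  VERY_STRONG = "VeryStrong", STAND_ALONE = "StandAlone"
)

.acmg_catalogue <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' ACMG/AMP 2015 criterion catalogue
#'
#' @return Character vector of the 28 evidence criterion codes of the 2015
#'   guideline (PVS1, PS1-PS4, PM1-PM6, PP1-PP5, BA1, BS1-BS4, BP1-BP7).
#' @export
acmg_codes <- function() .acmg_catalogue

#' Evidence strength levels
#'
#' @return Character vector of strength tokens ordered from weakest
#'   (`SUPPORTING`) to strongest (`STAND_ALONE`).
#' @export
strength_levels <- function() .strength_levels

#' Rank of an evidence strength
#'
#' Total order SUPPORTING < MODERATE < STRONG < VERY_STRONG < STAND_ALONE.
#'
#' @param strength Character vector of strength tokens.
#' @return Integer ranks (1 = SUPPORTING ... 5 = STAND_ALONE).
#' @export
strength_rank <- function(strength) {
  r <- match(strength, .strength_levels)
  if (anyNA(r)) {
    stop("unknown evidence strength: ",
         paste(unique(strength[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Polarity of an ACMG criterion code
#'
#' @param code Character vector of criterion codes.
#' @return `"PATHOGENIC"` for P-prefixed codes, `"BENIGN"` for B-prefixed.
#' @export
criterion_polarity <- function(code) {
  .check_codes(code)
  ifelse(substr(code, 1L, 1L) == "P", "PATHOGENIC", "BENIGN")
}

.check_codes <- function(code) {
  bad <- setdiff(code, .acmg_catalogue)
  if (length(bad)) {
    stop("unknown ACMG criterion code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(code)
}

#' Default strength of an ACMG criterion
#'
#' The strength implied by the code prefix: PVS = Very Strong, PS/BS = Strong,
#' PM = Moderate, PP/BP = Supporting, BA = Stand-alone.
#'
#' @param code Character vector of criterion codes.
#' @return Character vector of strength tokens.
#' @export
#' @examples
#' default_strength(c("PP3", "BA1", "PS4"))
default_strength <- function(code) {
  .check_codes(code)
  prefix <- sub("[0-9]+$", "", code)
  unname(c(PVS = "VERY_STRONG", PS = "STRONG", PM = "MODERATE",
           PP = "SUPPORTING", BA = "STAND_ALONE", BS = "STRONG",
           BP = "SUPPORTING")[prefix])
}

#' Construct an evidence profile
#'
#' An evidence profile is the set of ACMG criteria applied to a variant, each
#' carrying an effective strength that may differ from the code's default
#' (e.g. `PP3` raised to `STRONG` by a calibrated predictor score). At most one
#' entry per criterion code is kept: supplying a duplicate code replaces the
#' previous strength (last one wins).
#'
#' @param codes Character vector of criterion codes.
#' @param strengths Character vector of strength tokens, recycled defaults from
#'   [default_strength()] when `NULL`.
#' @return An `evidence_profile`: a named character vector mapping code to
#'   effective strength.
#' @export
#' @examples
#' evidence_profile(c("PM2", "PP3"), c("MODERATE", "STRONG"))
evidence_profile <- function(codes = character(), strengths = NULL) {
  codes <- as.character(codes)
  .check_codes(codes)
  if (is.null(strengths)) strengths <- default_strength(codes)
  strengths <- as.character(strengths)
  if (length(strengths) != length(codes)) {
    stop("codes and strengths must have the same length", call. = FALSE)
  }
  strength_rank(strengths)
  # last occurrence wins (replacement semantics for duplicate codes)
  if (length(codes)) {
    keep <- !duplicated(codes, fromLast = TRUE)
    codes <- codes[keep]
    strengths <- strengths[keep]
  }
  bad_sa <- strengths == "STAND_ALONE" & codes != "BA1"
  if (any(bad_sa)) {
    stop("STAND_ALONE strength is reserved for BA1; offending code(s): ",
         paste(codes[bad_sa], collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(strengths, codes), class = "evidence_profile")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("<evidence_profile> ", format_evidence(x), "\n", sep = "")
  invisible(x)
}

#' Parse a serialized evidence profile
#'
#' Profiles serialize as comma-separated tokens `CODE` or `CODE_Strength`
#' (e.g. `"PM2,PP3_Strong,BS1"`). Strength suffixes `_Supporting`, `_Moderate`,
#' `_Strong`, `_VeryStrong`, `_StandAlone` are matched case-insensitively
#' (underscores and spaces inside the suffix are ignored, so `PP3_Very_Strong`
#' also parses); a bare code carries its default strength.
#'
#' @param x A single string (empty string or `NA` gives an empty profile).
#' @return An [evidence_profile()].
#' @export
#' @examples
#' parse_evidence("PM2,PP3_Strong,BS1")
parse_evidence <- function(x) {
  if (length(x) != 1L) stop("parse_evidence() expects a single string", call. = FALSE)
  if (is.na(x) || !nzchar(trimws(x))) return(evidence_profile())
  tokens <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  codes <- sub("_.*$", "", tokens)
  strengths <- default_strength(codes)
  has_suffix <- grepl("_", tokens, fixed = TRUE)
  if (any(has_suffix)) {
    key <- gsub("[^a-z]", "", tolower(sub("^[^_]*_", "", tokens[has_suffix])))
    lookup <- stats::setNames(names(.strength_suffixes),
                              gsub("[^a-z]", "", tolower(.strength_suffixes)))
    parsed <- lookup[key]
    if (anyNA(parsed)) {
      stop("unknown strength suffix in token(s): ",
           paste(tokens[has_suffix][is.na(parsed)], collapse = ", "),
           call. = FALSE)
    }
    strengths[has_suffix] <- parsed
  }
  evidence_profile(codes, strengths)
}

#' Serialize an evidence profile
#'
#' Inverse of [parse_evidence()]: codes at their default strength are emitted
#' bare, modified strengths carry a `_Strength` suffix. Codes are emitted in
#' catalogue order so serialization is canonical.
#'
#' @param profile An [evidence_profile()].
#' @return A single string.
#' @export
format_evidence <- function(profile) {
  if (!length(profile)) return("")
  ord <- order(match(names(profile), .acmg_catalogue))
  codes <- names(profile)[ord]
  strengths <- unname(profile[ord])
  suffix <- ifelse(strengths == default_strength(codes), "",
                   paste0("_", .strength_suffixes[strengths]))
  paste0(codes, suffix, collapse = ",")
}

#' Engine options for the combining rules
#'
#' @param single_bs_is_lb Treat a single Strong benign criterion, with no
#'   pathogenic evidence applied, as Likely Benign. The strict 2015 table
#'   leaves 1x Strong-benign unclassified; this laboratory-practice extension
#'   is on by default. It is suppressed whenever any pathogenic criterion is
#'   present so that e.g. PS1 + BS1 stays a conflict (VUS).
#' @param ba1_overrides BA1 (stand-alone benign) forces Benign even when
#'   pathogenic rules fire. On by default.
#' @return A list of class `acmg_options`.
#' @export
acmg_options <- function(single_bs_is_lb = TRUE, ba1_overrides = TRUE) {
  stopifnot(is.logical(single_bs_is_lb), length(single_bs_is_lb) == 1L,
            is.logical(ba1_overrides), length(ba1_overrides) == 1L)
  structure(list(single_bs_is_lb = single_bs_is_lb,
                 ba1_overrides = ba1_overrides),
            class = "acmg_options")
}

#' Classification tiers
#'
#' @return The five tiers ordered from the benign end to the pathogenic end:
#'   `B`, `LB`, `VUS`, `LP`, `P`.
#' @export
classification_tiers <- function() c("B", "LB", "VUS", "LP", "P")

.class_labels <- c(B = "Benign", LB = "Likely benign", VUS = "VUS",
                   LP = "Likely pathogenic", P = "Pathogenic")

#' Normalize a classification label
#'
#' Accepts the short tokens (`B`, `LB`, `VUS`, `LP`, `P`) or the human-readable
#' labels ("Benign", "Likely benign", "Uncertain significance", ...),
#' case-insensitively.
#'
#' @param x Character vector of labels.
#' @return Character vector of short tier tokens.
#' @export
normalize_class <- function(x) {
  key <- toupper(gsub("[^A-Za-z]", "", x))
  map <- c(B = "B", BENIGN = "B",
           LB = "LB", LIKELYBENIGN = "LB",
           VUS = "VUS", UNCERTAINSIGNIFICANCE = "VUS", UNCERTAIN = "VUS",
           VARIANTOFUNCERTAINSIGNIFICANCE = "VUS",
           LP = "LP", LIKELYPATHOGENIC = "LP",
           P = "P", PATHOGENIC = "P")
  out <- map[key]
  if (anyNA(out)) {
    stop("unrecognized classification label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# Count-level classifier. Counting is code-agnostic: a PP3 raised to STRONG
# fills a Strong pathogenic slot exactly as PS1 would. `any_path` gates the
# single-strong-benign extension.
.classify_counts <- function(nvs, ns, nm, np, ba, bs, bm, bp, opts, any_path) {
  path_p <- (nvs >= 1 && (ns >= 1 || nm >= 2 || (nm >= 1 && np >= 1) || np >= 2)) ||
    nvs >= 2 ||
    ns >= 2 ||
    (ns >= 1 && (nm >= 3 || (nm >= 2 && np >= 2) || (nm >= 1 && np >= 4)))
  path_lp <- (nvs >= 1 && nm >= 1) ||
    (ns >= 1 && (nm >= 1 || np >= 2)) ||
    nm >= 3 ||
    (nm >= 2 && np >= 2) ||
    (nm >= 1 && np >= 4)
  bs_total <- bs + ba
  bsup <- bm + bp  # a Moderate benign satisfies any Supporting requirement
  ben_b <- ba >= 1 || bs_total >= 2
  ben_lb <- (bs_total >= 1 && bsup >= 1) || bsup >= 2 ||
    (opts$single_bs_is_lb && bs_total >= 1 && !any_path)
  if (ba >= 1 && opts$ba1_overrides) return("B")
  if ((path_p || path_lp) && (ben_b || ben_lb)) return("VUS")
  if (path_p) return("P")
  if (path_lp) return("LP")
  if (ben_b) return("B")
  if (ben_lb) return("LB")
  "VUS"
}

#' Combine an evidence profile into a five-tier classification
#'
#' Applies the 2015 ACMG/AMP combining rules to the profile's effective
#' strengths. Counting is code-agnostic: a criterion's effective strength, not
#' its code, determines which slot it fills (so `PP3` at `VERY_STRONG` counts
#' exactly as PVS1 would). Pathogenic rules: 1 Very strong with (>=1 Strong, or
#' >=2 Moderate, or 1 Moderate + 1 Supporting, or >=2 Supporting); >=2 Very
#' strong; >=2 Strong; 1 Strong with (>=3 Moderate, or 2 Moderate + >=2
#' Supporting, or 1 Moderate + >=4 Supporting). Likely-pathogenic rules: 1 Very
#' strong + 1 Moderate; 1 Strong + 1-2 Moderate; 1 Strong + >=2 Supporting;
#' >=3 Moderate; 2 Moderate + >=2 Supporting; 1 Moderate + >=4 Supporting.
#' Benign: BA1 alone, or >=2 Strong benign. Likely benign: 1 Strong benign +
#' >=1 Supporting benign; >=2 Supporting benign; optionally a lone Strong
#' benign (see [acmg_options()]). A Moderate benign criterion satisfies a
#' Supporting-benign requirement. If rules fire on both polarities the evidence
#' conflicts and the result is VUS (unless BA1 overrides); if no rule fires the
#' result is VUS.
#'
#' @param profile An [evidence_profile()] (or a string parseable by
#'   [parse_evidence()]).
#' @param options An [acmg_options()] list.
#' @return One of `classification_tiers()`.
#' @export
#' @examples
#' combine_evidence(parse_evidence("PVS1,PS1"))   # "P"
#' combine_evidence(parse_evidence("PM1,PP3_Strong"))  # "LP"
#' combine_evidence(parse_evidence("BS1,BP4_Strong"))  # "B"
combine_evidence <- function(profile, options = acmg_options()) {
  if (is.character(profile) && !inherits(profile, "evidence_profile")) {
    profile <- parse_evidence(profile)
  }
  if (!length(profile)) return("VUS")
  codes <- names(profile)
  strengths <- unname(unclass(profile))
  rk <- strength_rank(strengths)
  pathogenic <- substr(codes, 1L, 1L) == "P"
  .classify_counts(
    nvs = sum(pathogenic & rk == 4L),
    ns  = sum(pathogenic & rk == 3L),
    nm  = sum(pathogenic & rk == 2L),
    np  = sum(pathogenic & rk == 1L),
    ba  = sum(!pathogenic & rk == 5L),
    bs  = sum(!pathogenic & rk == 3L),
    bm  = sum(!pathogenic & rk == 2L),
    bp  = sum(!pathogenic & rk == 1L),
    opts = options,
    any_path = any(pathogenic)
  )
}

# all multisets of 1..n_levels with at most `size` items, as count matrices
.strength_multisets <- function(max_items, n_levels = 4L) {
  out <- list(matrix(0L, nrow = 1L, ncol = n_levels))
  if (max_items >= 1L) {
    grids <- expand.grid(rep(list(0:max_items), n_levels))
    grids <- as.matrix(grids[rowSums(grids) >= 1 & rowSums(grids) <= max_items, ,
                             drop = FALSE])
    out[[2]] <- grids
  }
  m <- do.call(rbind, out)
  m <- m[order(rowSums(m), m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
  colnames(m) <- .strength_levels[seq_len(n_levels)]
  rownames(m) <- NULL
  m
}

.multiset_label <- function(counts) {
  lev <- colnames(counts)
  apply(counts, 1L, function(r) {
    nz <- which(r > 0)
    if (!length(nz)) return("-")
    paste0(r[nz], "x", lev[nz], collapse = "+")
  })
}

# deterministic synthetic codes for a strength multiset of one polarity
.codes_for_counts <- function(counts, polarity) {
  pool <- if (polarity == "PATHOGENIC") {
    c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
  } else {
    c(paste0("BS", 1:4), paste0("BP", 1:7))
  }
  n <- sum(counts)
  if (n > length(pool)) stop("max_items too large for the code pool", call. = FALSE)
  strengths <- rep(names(counts), counts)
  list(codes = pool[seq_len(n)], strengths = strengths)
}

#' Enumerate the combining-rule table
#'
#' Deterministically enumerates every strength multiset with up to `max_items`
#' criteria per polarity (over the four orderable strengths Supporting,
#' Moderate, Strong, Very strong; BA1's stand-alone level is excluded) and
#' records the classification [combine_evidence()] assigns to each pathogenic
#' x benign combination. Intended for exhaustive testing and documentation of
#' the rule surface.
#'
#' @param max_items Maximum criteria per polarity (>= 0).
#' @param polarity `"both"`, `"pathogenic"` or `"benign"`; the one-polarity
#'   forms keep the other side empty.
#' @param options An [acmg_options()] list.
#' @return A data.frame with columns `pathogenic`, `benign` (multiset labels
#'   like `"1xSTRONG+2xSUPPORTING"`, `"-"` for empty) and `classification`.
#' @export
enumerate_rule_table <- function(max_items,
                                 polarity = c("both", "pathogenic", "benign"),
                                 options = acmg_options()) {
  polarity <- match.arg(polarity)
  stopifnot(length(max_items) == 1L, max_items >= 0)
  max_items <- as.integer(max_items)
  sets <- .strength_multisets(max_items)
  empty <- sets[1L, , drop = FALSE]
  p_sets <- if (polarity == "benign") empty else sets
  b_sets <- if (polarity == "pathogenic") empty else sets
  rows <- vector("list", nrow(p_sets) * nrow(b_sets))
  k <- 0L
  for (i in seq_len(nrow(p_sets))) {
    pc <- .codes_for_counts(p_sets[i, ], "PATHOGENIC")
    for (j in seq_len(nrow(b_sets))) {
      bc <- .codes_for_counts(b_sets[j, ], "BENIGN")
      prof <- evidence_profile(c(pc$codes, bc$codes), c(pc$strengths, bc$strengths))
      k <- k + 1L
      rows[[k]] <- list(i = i, j = j, cls = combine_evidence(prof, options))
    }
  }
  data.frame(
    pathogenic = .multiset_label(p_sets)[vapply(rows, `[[`, 1L, "i")],
    benign = .multiset_label(b_sets)[vapply(rows, `[[`, 1L, "j")],
    classification = vapply(rows, `[[`, "", "cls"),
    stringsAsFactors = FALSE
  )
}
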
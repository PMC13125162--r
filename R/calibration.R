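# Calibrated predictor-score thresholds: loading/validating the interval
# tables and mapping raw scores to PP3/BP4 evidence assignments.

.assign_values <- c("PP3", "BP4", "NONE")

#' Path to the shipped calibration config
#'
#' @return Path to the YAML file transcribing the ClinGen-recalibrated score
#'   thresholds shipped with the package.
#' @export
default_calibration_path <- function() {
  system.file("extdata", "clingen_calibration.yaml", package = "vusreclass",
              mustWork = TRUE)
}

# signed evidence rank along the deleterious direction:
# BP4 strengths are negative, NONE is 0, PP3 strengths positive.
.signed_rank <- function(assign, strength) {
  out <- integer(length(assign))
  has <- assign != "NONE"
  out[has] <- strength_rank(strength[has]) *
    ifelse(assign[has] == "PP3", 1L, -1L)
  out
}

.validate_predictor <- function(name, spec) {
  for (field in c("orientation", "range", "intervals")) {
    if (is.null(spec[[field]])) {
      stop("calibration for ", name, ": missing field '", field, "'",
           call. = FALSE)
    }
  }
  orientation <- toupper(spec$orientation)
  if (!orientation %in% c("HIGHER_IS_DELETERIOUS", "LOWER_IS_DELETERIOUS")) {
    stop("calibration for ", name, ": unknown orientation '",
         spec$orientation, "'", call. = FALSE)
  }
  range <- as.numeric(spec$range)
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("calibration for ", name, ": range must be two increasing finite numbers",
         call. = FALSE)
  }
  iv <- spec$intervals
  if (!length(iv)) stop("calibration for ", name, ": no intervals", call. = FALSE)
  df <- data.frame(
    lo = vapply(iv, function(x) as.numeric(x$lo), 0),
    lo_incl = vapply(iv, function(x) isTRUE(x$lo_incl), NA),
    hi = vapply(iv, function(x) as.numeric(x$hi), 0),
    hi_incl = vapply(iv, function(x) isTRUE(x$hi_incl), NA),
    assign = toupper(vapply(iv, function(x) as.character(x$assign), "")),
    strength = vapply(iv, function(x) {
      s <- x$strength
      if (is.null(s)) NA_character_ else as.character(s)
    }, ""),
    stringsAsFactors = FALSE
  )
  bad <- !df$assign %in% .assign_values
  if (any(bad)) {
    stop("calibration for ", name, ": unknown assignment '",
         df$assign[bad][1], "'", call. = FALSE)
  }
  none_with_strength <- df$assign == "NONE" & !is.na(df$strength)
  if (any(none_with_strength)) {
    stop("calibration for ", name,
         ": interval with assignment NONE must not carry a strength",
         call. = FALSE)
  }
  missing_strength <- df$assign != "NONE" & is.na(df$strength)
  if (any(missing_strength)) {
    stop("calibration for ", name, ": evidence-bearing interval without a strength",
         call. = FALSE)
  }
  # canonicalize strength tokens ("Strong" -> "STRONG", "VeryStrong" -> "VERY_STRONG")
  has_s <- !is.na(df$strength)
  if (any(has_s)) {
    key <- gsub("[^a-z]", "", tolower(df$strength[has_s]))
    lookup <- stats::setNames(names(.strength_suffixes),
                              gsub("[^a-z]", "", tolower(.strength_suffixes)))
    canon <- lookup[key]
    if (anyNA(canon)) {
      stop("calibration for ", name, ": unknown strength '",
           df$strength[has_s][is.na(canon)][1], "'", call. = FALSE)
    }
    if (any(canon == "STAND_ALONE")) {
      stop("calibration for ", name,
           ": computational evidence cannot be STAND_ALONE", call. = FALSE)
    }
    df$strength[has_s] <- unname(canon)
  }
  df <- df[order(df$lo, df$hi), , drop = FALSE]
  rownames(df) <- NULL
  # disjointness + joint coverage of the score range
  eps <- 1e-12
  if (abs(df$lo[1] - range[1]) > eps || !df$lo_incl[1]) {
    stop("calibration for ", name, ": intervals do not cover the lower range bound",
         call. = FALSE)
  }
  if (abs(df$hi[nrow(df)] - range[2]) > eps || !df$hi_incl[nrow(df)]) {
    stop("calibration for ", name, ": intervals do not cover the upper range bound",
         call. = FALSE)
  }
  if (nrow(df) > 1L) {
    for (i in seq_len(nrow(df) - 1L)) {
      if (abs(df$hi[i] - df$lo[i + 1L]) > eps) {
        stop("calibration for ", name, ": gap or overlap between intervals ",
             i, " and ", i + 1L, " (", df$hi[i], " vs ", df$lo[i + 1L], ")",
             call. = FALSE)
      }
      if (df$hi_incl[i] == df$lo_incl[i + 1L]) {
        stop("calibration for ", name, ": boundary ", df$hi[i],
             " between intervals ", i, " and ", i + 1L,
             " must be inclusive on exactly one side", call. = FALSE)
      }
    }
  }
  # orientation-aware monotonicity: along the deleterious direction evidence
  # moves BP4-strong -> BP4-weak -> NONE -> PP3-weak -> PP3-strong.
  sr <- .signed_rank(df$assign, df$strength)
  ordered <- if (orientation == "HIGHER_IS_DELETERIOUS") sr else rev(sr)
  if (is.unsorted(ordered, strictly = FALSE)) {
    stop("calibration for ", name,
         ": evidence strengths are not monotone along the deleterious direction",
         call. = FALSE)
  }
  list(
    name = name,
    orientation = orientation,
    range = range,
    model_variant = spec$model_variant,
    provenance = if (is.null(spec$provenance)) "" else spec$provenance,
    intervals = df
  )
}

#' Load and validate a calibration table
#'
#' Reads a YAML calibration config (predictor -> orientation, score range and
#' an ordered list of score intervals, each assigning PP3/BP4 evidence at a
#' strength, or NONE). Validation enforces: intervals pairwise disjoint and
#' jointly covering the score range, each internal boundary inclusive on
#' exactly one side, strength present iff the assignment is PP3/BP4, and
#' orientation-aware monotonicity (along the deleterious direction BP4
#' evidence weakens, passes through NONE, then PP3 evidence strengthens).
#'
#' @param path Path to a YAML config; defaults to the shipped transcription of
#'   the ClinGen recalibrations.
#' @return A `calibration_table`: named list of validated predictor entries.
#' @export
#' @examples
#' tab <- load_calibration()
#' names(tab)
load_calibration <- function(path = default_calibration_path()) {
  doc <- yaml::read_yaml(path)
  preds <- doc$predictors
  if (is.null(preds) || !length(preds)) {
    stop("calibration config has no 'predictors' section", call. = FALSE)
  }
  entries <- lapply(names(preds), function(nm) .validate_predictor(nm, preds[[nm]]))
  names(entries) <- names(preds)
  structure(entries, class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("<calibration_table> ", length(x), " predictors: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predictor names in a calibration table
#'
#' @param table A `calibration_table`.
#' @return Character vector of predictor names.
#' @export
calibration_predictors <- function(table = load_calibration()) names(table)

.in_interval <- function(score, row) {
  lo_ok <- if (row$lo_incl) score >= row$lo else score > row$lo
  hi_ok <- if (row$hi_incl) score <= row$hi else score < row$hi
  lo_ok && hi_ok
}

#' Map a predictor score to a PP3/BP4 evidence assignment
#'
#' Locates the unique calibration interval containing `score` and returns its
#' assignment. Boundary scores resolve per the interval inclusivity flags; in
#' the shipped config thresholds are inclusive on the evidence-bearing side.
#'
#' @param predictor Predictor name present in `table`.
#' @param score Numeric scores (vectorized; `NA` passes through as a missing
#'   assignment).
#' @param table A `calibration_table`.
#' @return A data.frame with columns `assign` (`"PP3"`, `"BP4"`, `"NONE"`, or
#'   `NA` for missing score) and `strength` (strength token or `NA`).
#' @export
#' @examples
#' map_score("VARITY", 0.021316)  # BP4 at STRONG
#' map_score("REVEL", c(0.014, 0.5, 0.95))
map_score <- function(predictor, score, table = load_calibration()) {
  if (!predictor %in% names(table)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  entry <- table[[predictor]]
  iv <- entry$intervals
  assign <- rep(NA_character_, length(score))
  strength <- rep(NA_character_, length(score))
  for (k in seq_along(score)) {
    s <- score[k]
    if (is.na(s)) next
    if (s < entry$range[1] || s > entry$range[2]) {
      stop("score ", s, " outside the declared range [", entry$range[1], ", ",
           entry$range[2], "] for predictor ", predictor, call. = FALSE)
    }
    for (i in seq_len(nrow(iv))) {
      if (.in_interval(s, iv[i, ])) {
        assign[k] <- iv$assign[i]
        strength[k] <- iv$strength[i]
        break
      }
    }
  }
  data.frame(assign = assign, strength = strength, stringsAsFactors = FALSE)
}

.variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Attach predictor scores to a variant table
#'
#' Left-joins a score annotation table onto variants by the GRCh37 identity
#' key (chrom, pos, ref, alt). Variants without a matching annotation keep
#' missing scores; a per-predictor missingness count is recorded in the
#' `"missingness"` attribute and reported via `message()`.
#'
#' @param variants Variant data.frame with columns `chrom, pos, ref, alt`.
#' @param annotations Score data.frame with columns `chrom, pos, ref, alt`
#'   plus one numeric column per predictor.
#' @param predictors Predictor columns to carry over; defaults to every
#'   non-key column of `annotations`.
#' @return `variants` with one `score_<predictor>` column per predictor and a
#'   `"missingness"` attribute (named integer vector).
#' @export
annotate_scores <- function(variants, annotations, predictors = NULL) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(key_cols %in% names(variants)), all(key_cols %in% names(annotations)))
  if (is.null(predictors)) predictors <- setdiff(names(annotations), key_cols)
  akey <- .variant_key(annotations)
  if (anyDuplicated(akey)) {
    stop("duplicate annotation key(s): ",
         paste(unique(akey[duplicated(akey)]), collapse = ", "), call. = FALSE)
  }
  idx <- match(.variant_key(variants), akey)
  miss <- integer(0)
  for (p in predictors) {
    val <- rep(NA_real_, nrow(variants))
    matched <- !is.na(idx)
    val[matched] <- as.numeric(annotations[[p]][idx[matched]])
    variants[[paste0("score_", p)]] <- val
    miss[p] <- sum(is.na(val))
  }
  attr(variants, "missingness") <- miss
  message("annotate_scores: per-predictor missing scores: ",
          paste(names(miss), miss, sep = "=", collapse = ", "))
  variants
}
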
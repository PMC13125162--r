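# Tabular I/O: tab-separated UTF-8 with header rows; missing values are
# empty cells. Variant identity is (chrom, pos, ref, alt) on GRCh37;
# duplicates are allowed across datasets but rejected within one.

.variant_cols <- c("chrom", "pos", "ref", "alt", "gene", "hgnc", "transcript",
                   "hgvs_c", "dataset", "moi", "baseline_class", "evidence")

.moi_levels <- c("AD", "AR", "XL", "UNKNOWN")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a curated variant table
#'
#' Tab-separated, header `chrom pos ref alt gene hgnc transcript hgvs_c
#' dataset moi baseline_class evidence`; the evidence column uses the token
#' format of [parse_evidence()]. Classifications are normalized to short tier
#' tokens, every evidence string is validated, and each record's curated
#' classification is checked against the engine: records whose label
#' disagrees with [combine_evidence()] of their profile are kept as reported
#' but flagged in the `as_reported` column (count reported via `message()`).
#' Duplicate (chrom, pos, ref, alt) keys within one dataset are rejected.
#'
#' @param path Path to the TSV file.
#' @param options [acmg_options()] used for the consistency check.
#' @return A variant data.frame with normalized `baseline_class`, validated
#'   `evidence`, and logical `as_reported`.
#' @export
read_variant_table <- function(path, options = acmg_options()) {
  df <- .read_tsv(path)
  missing_cols <- setdiff(.variant_cols, names(df))
  if (length(missing_cols)) {
    stop("variant table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .variant_cols, drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$evidence[is.na(df$evidence)] <- ""
  df$moi <- toupper(df$moi)
  df$moi[is.na(df$moi) | !df$moi %in% .moi_levels] <- "UNKNOWN"
  key_in_ds <- paste(df$dataset, df$chrom, df$pos, df$ref, df$alt, sep = ":")
  if (anyDuplicated(key_in_ds)) {
    stop("duplicate variant key(s) within a dataset: ",
         paste(unique(key_in_ds[duplicated(key_in_ds)]), collapse = ", "),
         call. = FALSE)
  }
  df$baseline_class <- normalize_class(df$baseline_class)
  engine_class <- vapply(df$evidence, function(e) {
    combine_evidence(parse_evidence(e), options)
  }, "", USE.NAMES = FALSE)
  df$as_reported <- engine_class != df$baseline_class
  if (any(df$as_reported)) {
    message("read_variant_table: ", sum(df$as_reported),
            " record(s) kept as reported (curated class differs from the engine)")
  }
  df
}

#' Write a variant table
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  .write_tsv(variants[, intersect(c(.variant_cols, "as_reported"),
                                  names(variants)), drop = FALSE], path)
  invisible(path)
}

#' Read a predictor score table
#'
#' Tab-separated with columns `chrom, pos, ref, alt` plus one score column
#' per predictor (blank cell = missing). Tool-specific column headers (e.g.
#' OpenCRAVAT-style `revel.score`) are mapped to canonical predictor names
#' via `aliases`.
#'
#' @param path Path to the TSV file.
#' @param aliases Optional named character vector mapping file column name ->
#'   canonical predictor name.
#' @return A data.frame with numeric score columns; duplicate variant keys
#'   are rejected.
#' @export
read_score_table <- function(path, aliases = NULL) {
  df <- .read_tsv(path)
  key_cols <- c("chrom", "pos", "ref", "alt")
  if (!all(key_cols %in% names(df))) {
    stop("score table ", path, " must have columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  if (!is.null(aliases)) {
    hit <- names(df) %in% names(aliases)
    names(df)[hit] <- unname(aliases[names(df)[hit]])
  }
  df$pos <- as.integer(df$pos)
  key <- .variant_key(df)
  if (anyDuplicated(key)) {
    stop("duplicate score-table key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(df), key_cols)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a predictor score table
#'
#' @param scores Score data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  .write_tsv(scores, path)
  invisible(path)
}

#' Read variants from a VCF 4.2 file
#'
#' Accepts VCF with INFO keys `EVID` (evidence tokens, comma-separated),
#' `DATASET`, `MOI` and `BASECLASS` carrying the same values as the variant
#' table columns. Requires the vcfR package.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param options [acmg_options()] for the consistency check.
#' @return A variant data.frame as from [read_variant_table()].
#' @export
read_variants_vcf <- function(path, options = acmg_options()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants_vcf() requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  df <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    gene = NA_character_, hgnc = NA_character_, transcript = NA_character_,
    hgvs_c = NA_character_,
    dataset = info_get("DATASET"),
    moi = info_get("MOI"),
    baseline_class = info_get("BASECLASS"),
    evidence = info_get("EVID"),
    stringsAsFactors = FALSE
  )
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  .write_tsv(df, tmp)
  read_variant_table(tmp, options)
}

#' Write reclassification outcomes
#'
#' @param outcomes Outcome data.frame (one row per variant x predictor).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  .write_tsv(outcomes, path)
  invisible(path)
}

#' Write transition matrices in long form
#'
#' One row per (dataset, predictor, old tier, new tier) with a positive
#' count.
#'
#' @param outcomes Stacked outcome data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(outcomes, path) {
  combos <- unique(outcomes[, c("dataset", "predictor")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- outcomes[outcomes$dataset == combos$dataset[i] &
                      outcomes$predictor == combos$predictor[i], , drop = FALSE]
    tm <- transition_matrix(sub)
    long <- as.data.frame(tm, stringsAsFactors = FALSE)
    names(long) <- c("old_class", "new_class", "count")
    long <- long[long$count > 0, , drop = FALSE]
    if (nrow(long)) {
      rows[[length(rows) + 1L]] <- cbind(
        dataset = combos$dataset[i], predictor = combos$predictor[i], long,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset = character(), predictor = character(),
               old_class = character(), new_class = character(),
               count = integer())
  .write_tsv(out, path)
  invisible(path)
}

# structured run log: config used plus bookkeeping counters
.write_run_log <- function(out_dir, subcommand, config, counters = list()) {
  log <- list(subcommand = subcommand, config = config, counters = counters,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(NULL)
}
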
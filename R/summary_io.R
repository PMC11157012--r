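# Reading, validating and writing per-variant GWAS summary-statistics tables.
#
# The exchange dialect is the common tab-delimited summary-statistics layout:
# one row per biallelic SNP with columns
#   variant_id, effect_allele, other_allele, eaf, beta, se, pval, n
# plus optional chrom/pos (1-based) used only for clumping windows. "NA" and
# "." are accepted as missing.

CANONICAL_COLS <- c(
  "variant_id", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n", "chrom", "pos"
)
MANDATORY_COLS <- c(
  "variant_id", "effect_allele", "other_allele", "eaf", "beta", "se", "pval"
)

#' Construct a validated summary-statistics object
#'
#' A `summary_stats` object holds the per-variant association table for one
#' trait: the unit of input for instrument selection and the unit of output
#' for the synthetic generator. Rows failing the per-variant invariants
#' (positive se, frequency in (0,1), p in (0,1], distinct single-letter
#' alleles -- indels and multi-allelic records are rejected, duplicate
#' variant ids) are dropped with a message giving the count per reason.
#'
#' @param records data.frame with at least the mandatory columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`; optionally `n`, `chrom`, `pos`.
#' @param trait_id character label for the trait.
#' @param effect_scale `"log_odds"` (binary trait) or `"sd_units"`
#'   (continuous trait). Declared metadata, never inferred from the data.
#' @param sample_size_default optional positive integer used where `n` is
#'   missing.
#' @param quiet suppress the dropped-row message.
#' @return An object of class `summary_stats`: a list with elements
#'   `trait_id`, `records` (validated data.frame), `effect_scale`,
#'   `sample_size_default`, and a `dropped` attrition table.
#' @export
summary_stats <- function(records, trait_id,
                          effect_scale = c("log_odds", "sd_units"),
                          sample_size_default = NULL,
                          quiet = FALSE) {
  effect_scale <- match.arg(effect_scale)
  if (!is.data.frame(records)) {
    mr_stop("mr_config_error", "`records` must be a data.frame")
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols)) {
    mr_stop("mr_config_error", paste0(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in setdiff(CANONICAL_COLS, names(records))) {
    records[[col]] <- NA
  }
  records <- records[CANONICAL_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$n <- suppressWarnings(as.numeric(records$n))
  records$pos <- suppressWarnings(as.numeric(records$pos))
  records$chrom <- as.character(records$chrom)

  val <- validate_variant_records(records)
  if (!quiet && nrow(val$dropped) > 0) {
    tab <- table(val$dropped$reason)
    message(
      "summary_stats[", trait_id, "]: dropped ", nrow(val$dropped),
      " invalid row(s) (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")"
    )
  }
  if (nrow(val$records) == 0) {
    mr_stop("mr_empty_input",
            paste0("no valid rows for trait '", trait_id, "'"))
  }
  rownames(val$records) <- NULL
  structure(
    list(
      trait_id = trait_id,
      records = val$records,
      effect_scale = effect_scale,
      sample_size_default = sample_size_default
    ),
    dropped = val$dropped,
    class = "summary_stats"
  )
}

# Row-local invariant checks; returns kept records plus the dropped rows
# tagged with the first violated rule.
validate_variant_records <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !(df$effect_allele %in% ALLELES) |
    !(df$other_allele %in% ALLELES)
  reason[is.na(reason) & bad_allele] <- "non_snp_allele"
  same <- !bad_allele & df$effect_allele == df$other_allele
  reason[is.na(reason) & same] <- "identical_alleles"
  reason[is.na(reason) & (is.na(df$se) | df$se <= 0)] <- "nonpositive_se"
  reason[is.na(reason) & (is.na(df$eaf) | df$eaf <= 0 | df$eaf >= 1)] <-
    "eaf_out_of_range"
  reason[is.na(reason) & (is.na(df$pval) | df$pval <= 0 | df$pval > 1)] <-
    "pval_out_of_range"
  reason[is.na(reason) & (is.na(df$beta) | !is.finite(df$beta))] <-
    "nonfinite_beta"
  reason[is.na(reason) & duplicated(df$variant_id)] <- "duplicate_variant_id"
  keep <- is.na(reason)
  list(
    records = df[keep, , drop = FALSE],
    dropped = cbind(df[!keep, , drop = FALSE],
                    reason = reason[!keep])
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> trait:", x$trait_id,
      "| scale:", x$effect_scale,
      "| variants:", nrow(x$records), "\n")
  invisible(x)
}

#' Number of variant records
#' @param stats a `summary_stats` object.
#' @return integer count.
#' @export
n_variants <- function(stats) nrow(stats$records)

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file, renames columns through `column_map`, and
#' validates the result (see [summary_stats()]). Alleles are upper-cased;
#' `"."` and `"NA"` are treated as missing.
#'
#' @param path file path to a delimited table with a header.
#' @param trait_id trait label attached to the result.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(variant_id = "SNP", beta = "b")`. Canonical
#'   names absent from the map are assumed to appear verbatim in the header.
#' @param sep field separator (default tab).
#' @param effect_scale,sample_size_default,quiet passed to [summary_stats()].
#' @return A `summary_stats` object.
#' @export
read_summary_table <- function(path, trait_id, column_map = NULL,
                               sep = "\t",
                               effect_scale = c("log_odds", "sd_units"),
                               sample_size_default = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    mr_stop("mr_io_error", paste0("file not found: ", path))
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", "."),
                           check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      mr_stop("mr_config_error", paste0(
        "mapped column(s) absent from header: ",
        paste(missing_src, collapse = ", ")
      ))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(raw))
  if (length(missing_cols)) {
    mr_stop("mr_config_error", paste0(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  summary_stats(raw, trait_id = trait_id, effect_scale = effect_scale,
                sample_size_default = sample_size_default, quiet = quiet)
}

#' Write a summary-statistics table
#'
#' Emits the canonical tab-delimited layout. Numeric fields are written with
#' 17 significant digits so a write/read round trip reproduces every value
#' exactly; missing `n` is written as `NA`.
#'
#' @param stats a `summary_stats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- stats$records
  cols <- c("variant_id", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  if (any(!is.na(df$chrom)) || any(!is.na(df$pos))) {
    cols <- c(cols, "chrom", "pos")
  }
  out <- df[cols]
  for (col in intersect(c("eaf", "beta", "se", "pval", "n", "pos"), cols)) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    mr_stop("mr_io_error", paste0("cannot write to ", path, ": ",
                                  conditionMessage(ok)))
  }
  invisible(path)
}

#' Read per-trait column maps from a YAML config
#'
#' The config is a mapping from trait id to a `canonical: file_column`
#' mapping, matching the `column_map` argument of [read_summary_table()].
#'
#' @param path YAML file path.
#' @return named list of named character vectors.
#' @export
read_column_maps <- function(path) {
  if (!file.exists(path)) {
    mr_stop("mr_io_error", paste0("file not found: ", path))
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(m) unlist(m))
}
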
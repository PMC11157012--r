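# Instrument selection and exposure-outcome harmonization.
#
# Selection follows the conventional pipeline for summary-level MR:
#   1. genome-wide significance (p < 5e-8, strict),
#   2. LD clumping (r^2 < 0.001 within a 10,000 kb window, greedy on p),
#   3. MAF <= 0.01 and palindromic (A/T, C/G) variants excluded,
#   4. per-SNP F-statistic beta^2/se^2, F < 10 excluded,
# then harmonization of outcome effects onto the exposure's effect alleles.

# ---- subsetting helper -------------------------------------------------

subset_stats <- function(stats, keep) {
  stats$records <- stats$records[keep, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Select variants by association p-value
#'
#' Retains exactly the rows with `pval < threshold` (strict inequality, per
#' the genome-wide-significance convention). An empty result is allowed;
#' downstream stages decide what to do with it.
#'
#' @param stats a `summary_stats` object.
#' @param threshold p-value threshold in (0,1); default genome-wide
#'   significance `5e-8`.
#' @return A `summary_stats` subset.
#' @export
select_by_pvalue <- function(stats, threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    mr_stop("mr_config_error", "`threshold` must lie in (0, 1)")
  }
  subset_stats(stats, stats$records$pval < threshold)
}

#' Drop low-frequency and palindromic variants
#'
#' Removes rows whose minor-allele frequency `min(eaf, 1 - eaf)` is `<=
#' maf_min` (inclusive exclusion) and rows whose allele pair is A/T or C/G
#' (palindromic; strand cannot be resolved from alleles alone, so these are
#' dropped outright rather than frequency-inferred).
#'
#' @param stats a `summary_stats` object with `eaf` present for all rows.
#' @param maf_min MAF exclusion bound, default `0.01`.
#' @return A `summary_stats` subset.
#' @export
filter_maf_and_palindromes <- function(stats, maf_min = 0.01) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- stats$records
  maf <- pmin(df$eaf, 1 - df$eaf)
  keep <- maf > maf_min & !is_palindromic(df$effect_allele, df$other_allele)
  subset_stats(stats, keep)
}

#' Per-SNP instrument strength (F-statistic) filter
#'
#' Computes `F = beta^2 / se^2` for each variant and removes those with
#' `F < f_threshold`. The surviving rows, with their F statistics, form the
#' instrument set for one exposure.
#'
#' @param stats a `summary_stats` object (the exposure table).
#' @param f_threshold weak-instrument bound, default `10`.
#' @param quiet suppress the mean-F message.
#' @return A data.frame of class `instrument_set` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf_exp`, `beta_exp`,
#'   `se_exp`, `pval_exp`, `f_stat`, `chrom`, `pos`; attribute
#'   `exposure_id`.
#' @export
compute_f_statistics <- function(stats, f_threshold = 10, quiet = FALSE) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- stats$records
  f_stat <- df$beta^2 / df$se^2
  keep <- f_stat >= f_threshold
  out <- data.frame(
    variant_id = df$variant_id[keep],
    effect_allele = df$effect_allele[keep],
    other_allele = df$other_allele[keep],
    eaf_exp = df$eaf[keep],
    beta_exp = df$beta[keep],
    se_exp = df$se[keep],
    pval_exp = df$pval[keep],
    f_stat = f_stat[keep],
    chrom = df$chrom[keep],
    pos = df$pos[keep],
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    message(
      "instruments[", stats$trait_id, "]: ", nrow(out), "/", nrow(df),
      " SNPs with F >= ", f_threshold,
      if (nrow(out)) paste0(" (mean F = ", round(mean(out$f_stat), 1), ")")
      else ""
    )
  }
  structure(out, exposure_id = stats$trait_id, class = c("instrument_set",
                                                         "data.frame"))
}

# ---- LD ----------------------------------------------------------------

#' Pairwise LD (r-squared) lookup
#'
#' Wraps a symmetric r-squared matrix with unit diagonal. Missing pairs stay
#' `NA`: [ld_clump()] raises a hard error rather than silently assuming
#' independence when it needs a pair that is absent.
#'
#' @param r2 square numeric matrix of r-squared values with variant ids as
#'   dimnames (values in \[0,1\], symmetric, diagonal 1).
#' @return An `ld_info` object.
#' @export
ld_info <- function(r2) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) {
    mr_stop("mr_config_error", "`r2` must be a square matrix")
  }
  if (is.null(rownames(r2)) || is.null(colnames(r2))) {
    mr_stop("mr_config_error", "`r2` needs variant ids as dimnames")
  }
  vals <- r2[!is.na(r2)]
  if (any(vals < 0 | vals > 1)) {
    mr_stop("mr_config_error", "r-squared values must lie in [0, 1]")
  }
  if (!isTRUE(all.equal(r2, t(r2)))) {
    mr_stop("mr_config_error", "r-squared matrix must be symmetric")
  }
  if (any(abs(diag(r2) - 1) > 1e-12)) {
    mr_stop("mr_config_error", "r-squared diagonal must be 1")
  }
  structure(list(r2 = r2, ids = rownames(r2)), class = "ld_info")
}

#' Look up pairwise r-squared
#' @param ld an `ld_info` object.
#' @param id_a,id_b variant ids.
#' @return r-squared, or `NA` when the pair is not covered.
#' @export
ld_r2 <- function(ld, id_a, id_b) {
  stopifnot(inherits(ld, "ld_info"))
  if (!(id_a %in% ld$ids) || !(id_b %in% ld$ids)) return(NA_real_)
  ld$r2[id_a, id_b]
}

#' Read an LD file
#'
#' Accepts either a dense matrix with variant-id header and row names, or a
#' three-column pair list `id_a<TAB>id_b<TAB>r2` (unlisted pairs are treated
#' as missing, not as zero).
#'
#' @param path file path.
#' @return An `ld_info` object.
#' @export
read_ld_file <- function(path) {
  if (!file.exists(path)) {
    mr_stop("mr_io_error", paste0("file not found: ", path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  pair_header <- length(header) == 3 &&
    tolower(header[3]) %in% c("r2", "r^2", "rsq", "r.squared")
  pair_headerless <- length(header) == 3 &&
    suppressWarnings(!is.na(as.numeric(header[3])))
  if (pair_header || pair_headerless) {
    df <- utils::read.delim(path, header = pair_header,
                            stringsAsFactors = FALSE,
                            col.names = c("id_a", "id_b", "r2"))
    ids <- sort(unique(c(df$id_a, df$id_b)))
    r2 <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
    diag(r2) <- 1
    for (i in seq_len(nrow(df))) {
      r2[df$id_a[i], df$id_b[i]] <- df$r2[i]
      r2[df$id_b[i], df$id_a[i]] <- df$r2[i]
    }
    return(ld_info(r2))
  }
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  ld_info(m)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the lowest p-value and
#' discards every other variant with `r2 >= r2_max` lying within
#' `window_kb` of it (strictly: `|pos difference| < window_kb * 1000`, same
#' chromosome). Variants on different chromosomes, or farther apart than the
#' window, are never clumped against each other regardless of the LD lookup.
#' A pair inside the window with no LD entry is a hard error.
#'
#' @param stats a `summary_stats` object (positions in `chrom`/`pos` when
#'   the window rule is needed).
#' @param ld an `ld_info` object.
#' @param r2_max clumping threshold, default `0.001`.
#' @param window_kb window half-width in kb, default `10000`.
#' @return A `summary_stats` subset ordered by ascending p-value.
#' @export
ld_clump <- function(stats, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"), inherits(ld, "ld_info"))
  df <- stats$records
  if (nrow(df) <= 1) return(stats)
  ord <- order(df$pval)
  df <- df[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(df))
  kept <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    if (i == nrow(df)) break
    for (j in seq(i + 1L, nrow(df))) {
      if (!alive[j]) next
      in_window <- TRUE
      if (!is.na(df$chrom[i]) && !is.na(df$chrom[j]) &&
          !is.na(df$pos[i]) && !is.na(df$pos[j])) {
        in_window <- df$chrom[i] == df$chrom[j] &&
          abs(df$pos[i] - df$pos[j]) < window_bp
      }
      if (!in_window) next
      r2 <- ld_r2(ld, df$variant_id[i], df$variant_id[j])
      if (is.na(r2)) {
        mr_stop("mr_missing_ld", paste0(
          "no LD entry for pair within clumping window: ",
          df$variant_id[i], " / ", df$variant_id[j]
        ))
      }
      if (r2 >= r2_max) alive[j] <- FALSE
    }
  }
  stats$records <- df[kept, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

# ---- harmonization -----------------------------------------------------

#' Harmonize outcome effects onto the exposure's effect alleles
#'
#' Intersects instruments with the outcome table on `variant_id` and orients
#' each outcome effect to the exposure's effect allele. Four allele
#' configurations are resolvable for non-palindromic SNPs:
#' identical orientation (kept as is), swapped alleles (outcome beta
#' negated, frequency flipped), strand complement in the same orientation
#' (kept), and strand complement swapped (negated). Anything else -- and any
#' variant on a user-supplied exclusion list, the stand-in for a confounder
#' database screen -- is dropped with a logged reason. Palindromic SNPs are
#' removed upstream but dropped here too, defensively.
#'
#' @param instruments an `instrument_set` (see [compute_f_statistics()]).
#' @param outcome a `summary_stats` object for the outcome trait.
#' @param exclusion_list character vector of variant ids to exclude.
#' @param quiet suppress the attrition message.
#' @return A data.frame of class `harmonized_set` with one row per usable
#'   SNP: `variant_id`, `effect_allele`, `other_allele`, `beta_exp`,
#'   `se_exp`, `pval_exp`, `eaf_exp`, `f_stat`, `beta_out`, `se_out`,
#'   `eaf_out`; attributes `exposure_id`, `outcome_id`, `attrition`.
#' @export
harmonize <- function(instruments, outcome, exclusion_list = character(),
                      quiet = FALSE) {
  stopifnot(inherits(outcome, "summary_stats"))
  exp_df <- as.data.frame(instruments)
  needed <- c("variant_id", "effect_allele", "other_allele",
              "beta_exp", "se_exp")
  if (!all(needed %in% names(exp_df))) {
    mr_stop("mr_config_error", paste0(
      "`instruments` must carry columns: ", paste(needed, collapse = ", ")
    ))
  }
  if (!"f_stat" %in% names(exp_df)) {
    exp_df$f_stat <- exp_df$beta_exp^2 / exp_df$se_exp^2
  }
  if (!"pval_exp" %in% names(exp_df)) exp_df$pval_exp <- NA_real_
  if (!"eaf_exp" %in% names(exp_df)) exp_df$eaf_exp <- NA_real_
  attrition <- c(instruments = nrow(exp_df))

  excl <- exp_df$variant_id %in% exclusion_list
  attrition["excluded_by_list"] <- sum(excl)
  exp_df <- exp_df[!excl, , drop = FALSE]

  out_df <- outcome$records
  idx <- match(exp_df$variant_id, out_df$variant_id)
  attrition["absent_in_outcome"] <- sum(is.na(idx))
  exp_df <- exp_df[!is.na(idx), , drop = FALSE]
  out_df <- out_df[idx[!is.na(idx)], , drop = FALSE]

  pal <- is_palindromic(exp_df$effect_allele, exp_df$other_allele)
  attrition["palindromic"] <- sum(pal)
  exp_df <- exp_df[!pal, , drop = FALSE]
  out_df <- out_df[!pal, , drop = FALSE]

  ea <- exp_df$effect_allele
  oa <- exp_df$other_allele
  cea <- unname(COMPLEMENT[ea])
  coa <- unname(COMPLEMENT[oa])
  same <- out_df$effect_allele == ea & out_df$other_allele == oa
  swapped <- out_df$effect_allele == oa & out_df$other_allele == ea
  comp_same <- out_df$effect_allele == cea & out_df$other_allele == coa
  comp_swap <- out_df$effect_allele == coa & out_df$other_allele == cea
  flip <- swapped | comp_swap
  keep <- same | swapped | comp_same | comp_swap
  attrition["allele_mismatch"] <- sum(!keep)

  beta_out <- ifelse(flip, -out_df$beta, out_df$beta)
  eaf_out <- ifelse(flip, 1 - out_df$eaf, out_df$eaf)

  res <- data.frame(
    variant_id = exp_df$variant_id,
    effect_allele = ea,
    other_allele = oa,
    beta_exp = exp_df$beta_exp,
    se_exp = exp_df$se_exp,
    pval_exp = exp_df$pval_exp,
    eaf_exp = exp_df$eaf_exp,
    f_stat = exp_df$f_stat,
    beta_out = beta_out,
    se_out = out_df$se,
    eaf_out = eaf_out,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(res) <- NULL
  attrition["harmonized"] <- nrow(res)

  if (nrow(res) == 0) {
    mr_stop("mr_empty_set", paste0(
      "no harmonizable SNPs for ",
      attr(instruments, "exposure_id") %||% "exposure", " -> ",
      outcome$trait_id
    ), data = attrition)
  }
  if (!quiet) {
    message("harmonize[", attr(instruments, "exposure_id") %||% "exposure",
            " -> ", outcome$trait_id, "]: ",
            paste(names(attrition), attrition, sep = "=", collapse = ", "))
  }
  harmonized_set(res,
                 exposure_id = attr(instruments, "exposure_id") %||% "exposure",
                 outcome_id = outcome$trait_id,
                 attrition = attrition)
}

#' Construct a harmonized exposure-outcome set directly
#'
#' Low-level constructor used by [harmonize()] and by tests/simulations that
#' already hold aligned effect pairs.
#'
#' @param df data.frame with at least `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` (plus `variant_id`; one is synthesized if absent).
#' @param exposure_id,outcome_id trait labels.
#' @param attrition optional named attrition vector.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(df, exposure_id = "exposure",
                           outcome_id = "outcome", attrition = NULL) {
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(needed %in% names(df))) {
    mr_stop("mr_config_error", paste0(
      "harmonized set needs columns: ", paste(needed, collapse = ", ")
    ))
  }
  if (!"variant_id" %in% names(df)) {
    df$variant_id <- sprintf("snp_%03d", seq_len(nrow(df)))
  }
  if (any(df$se_exp <= 0) || any(df$se_out <= 0)) {
    mr_stop("mr_config_error", "standard errors must be positive")
  }
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            attrition = attrition,
            class = c("harmonized_set", "data.frame"))
}

#' Number of instruments in a harmonized set
#' @param hset a `harmonized_set`.
#' @return integer SNP count J.
#' @export
n_instruments <- function(hset) nrow(hset)
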
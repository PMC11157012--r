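# Multivariable MR: joint estimation of the direct effects of K exposures
# on one outcome from summary statistics.

#' Build a multivariable MR design
#'
#' Instrument union construction: SNPs genome-wide significant for at least
#' one exposure are pooled (each SNP carried once, with the minimum p
#' across exposures as its clumping p), jointly LD-clumped, passed through
#' the MAF/palindrome and F filters (frequency, alleles and F taken from
#' the defining exposure -- the one with the lowest p for that SNP), then
#' intersected with every exposure table and the outcome table and
#' allele-aligned to the defining orientation.
#'
#' @param exposures list of `summary_stats`, K >= 2 (a length-1 list is
#'   accepted for the degenerate K = 1 check).
#' @param outcome a `summary_stats` object.
#' @param ld an `ld_info` object, or NULL to skip clumping (e.g. when
#'   instruments are known to be independent by construction).
#' @param p_threshold,r2_max,window_kb,maf_min,f_threshold selection
#'   parameters as in the univariable pipeline.
#' @param exclusion_list variant ids to exclude.
#' @param quiet suppress progress messages.
#' @return A data.frame of class `mvmr_set` with columns `variant_id`,
#'   one `beta_<id>`/`se_<id>` pair per exposure, `beta_out`, `se_out`;
#'   attributes `exposure_ids`, `outcome_id`, `n_snp_per_exposure` (count
#'   of union SNPs genome-wide significant for each exposure -- the
#'   reported per-exposure instrument count).
#' @export
build_mvmr_design <- function(exposures, outcome, ld = NULL,
                              p_threshold = 5e-8, r2_max = 0.001,
                              window_kb = 10000, maf_min = 0.01,
                              f_threshold = 10,
                              exclusion_list = character(),
                              quiet = FALSE) {
  stopifnot(is.list(exposures), length(exposures) >= 1,
            inherits(outcome, "summary_stats"))
  K <- length(exposures)
  ids <- vapply(exposures, function(e) e$trait_id, character(1))
  if (anyDuplicated(ids)) {
    mr_stop("mr_config_error", "exposure trait ids must be unique")
  }

  # union of significant SNPs, keyed by minimum p across exposures
  sig <- lapply(exposures, function(e) select_by_pvalue(e, p_threshold))
  union_rows <- NULL
  for (k in seq_len(K)) {
    df <- sig[[k]]$records
    if (!nrow(df)) next
    df$.exposure <- ids[k]
    if (is.null(union_rows)) {
      union_rows <- df
    } else {
      new <- !(df$variant_id %in% union_rows$variant_id)
      union_rows <- rbind(union_rows, df[new, , drop = FALSE])
      # keep the lowest-p defining exposure per SNP
      shared <- df[!new, , drop = FALSE]
      if (nrow(shared)) {
        idx <- match(shared$variant_id, union_rows$variant_id)
        better <- shared$pval < union_rows$pval[idx]
        union_rows[idx[better], ] <- shared[better, , drop = FALSE]
      }
    }
  }
  if (is.null(union_rows) || nrow(union_rows) == 0) {
    mr_stop("mr_empty_set", "no genome-wide significant SNPs in any exposure")
  }
  defining <- union_rows$.exposure
  names(defining) <- union_rows$variant_id
  union_rows$.exposure <- NULL

  union_stats <- structure(
    list(trait_id = "mvmr_union", records = union_rows,
         effect_scale = outcome$effect_scale, sample_size_default = NULL),
    class = "summary_stats"
  )
  if (!is.null(ld)) {
    union_stats <- ld_clump(union_stats, ld, r2_max = r2_max,
                            window_kb = window_kb)
  }
  union_stats <- filter_maf_and_palindromes(union_stats, maf_min = maf_min)
  inst <- compute_f_statistics(union_stats, f_threshold = f_threshold,
                               quiet = quiet)
  inst <- inst[!(inst$variant_id %in% exclusion_list), , drop = FALSE]
  if (!nrow(inst)) mr_stop("mr_empty_set", "no instruments after filtering")

  # align every exposure and the outcome to the defining orientation
  ref <- data.frame(variant_id = inst$variant_id,
                    effect_allele = inst$effect_allele,
                    other_allele = inst$other_allele,
                    stringsAsFactors = FALSE)
  aligned <- lapply(exposures, function(e) align_to_reference(ref, e))
  out_al <- align_to_reference(ref, outcome)

  keep <- stats::complete.cases(
    do.call(cbind, c(lapply(aligned, function(a) a$beta), list(out_al$beta)))
  )
  if (sum(keep) == 0) {
    mr_stop("mr_empty_set", "no SNPs shared by all exposures and the outcome")
  }
  res <- data.frame(variant_id = ref$variant_id[keep],
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    res[[paste0("beta_", ids[k])]] <- aligned[[k]]$beta[keep]
    res[[paste0("se_", ids[k])]] <- aligned[[k]]$se[keep]
  }
  res$beta_out <- out_al$beta[keep]
  res$se_out <- out_al$se[keep]

  J <- nrow(res)
  if (K >= 2 && J <= K) {
    mr_stop("mr_underidentified", paste0(
      "only ", J, " SNPs for ", K, " exposures; design under-identified"
    ))
  }
  n_per <- vapply(seq_len(K), function(k) {
    sum(res$variant_id %in% sig[[k]]$records$variant_id)
  }, integer(1))
  names(n_per) <- ids
  if (!quiet) {
    message("mvmr design: J = ", J, " SNPs; per-exposure significant counts: ",
            paste(ids, n_per, sep = "=", collapse = ", "))
  }
  structure(res, exposure_ids = ids, outcome_id = outcome$trait_id,
            n_snp_per_exposure = n_per,
            class = c("mvmr_set", "data.frame"))
}

# Orient a trait's records onto reference alleles; NA beta where the SNP is
# absent or the allele pair is unresolvable. Same truth table as
# harmonize().
align_to_reference <- function(ref, stats) {
  df <- stats$records
  idx <- match(ref$variant_id, df$variant_id)
  ea <- ref$effect_allele
  oa <- ref$other_allele
  cea <- unname(COMPLEMENT[ea])
  coa <- unname(COMPLEMENT[oa])
  t_ea <- df$effect_allele[idx]
  t_oa <- df$other_allele[idx]
  same <- t_ea == ea & t_oa == oa
  swapped <- t_ea == oa & t_oa == ea
  comp_same <- t_ea == cea & t_oa == coa
  comp_swap <- t_ea == coa & t_oa == cea
  keep <- !is.na(idx) & (same | swapped | comp_same | comp_swap)
  flip <- swapped | comp_swap
  beta <- ifelse(keep, ifelse(flip, -df$beta[idx], df$beta[idx]), NA_real_)
  se <- ifelse(keep, df$se[idx], NA_real_)
  list(beta = beta, se = se)
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression of the outcome betas on the K exposure-beta
#' columns, no intercept, weights `1/se_out^2`. Each coefficient is the
#' direct effect of that exposure conditional on the others. Per-exposure
#' SEs use the multiplicative random-effects convention: inflation by
#' `max(1, sqrt(Q_res / (J - K)))` with Q_res the weighted residual sum of
#' squares (floored at 1 for consistency with univariable IVW, to which
#' this reduces exactly at K = 1). p-values are two-sided normal.
#'
#' @param design an `mvmr_set` from [build_mvmr_design()].
#' @return Named list of `mr_estimate` objects (method `"mvmr_ivw"`), one
#'   per exposure; `n_snp` is that exposure's significant-instrument count.
#' @export
mvmr_ivw <- function(design) {
  ids <- attr(design, "exposure_ids")
  K <- length(ids)
  J <- nrow(design)
  if (J <= K) {
    mr_stop("mr_underidentified", "J must exceed the number of exposures")
  }
  X <- as.matrix(design[paste0("beta_", ids)])
  colnames(X) <- ids
  y <- design$beta_out
  w <- 1 / design$se_out^2
  sw <- sqrt(w)
  Xw <- X * sw
  qr_x <- qr(Xw)
  if (qr_x$rank < K) {
    bad <- ids[qr_x$pivot[seq(qr_x$rank + 1, K)]]
    mr_stop("mr_collinearity", paste0(
      "collinear exposure betas; offending exposure(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  xtwx_inv <- chol2inv(chol(crossprod(Xw)))
  beta <- drop(xtwx_inv %*% crossprod(Xw, y * sw))
  resid <- y - drop(X %*% beta)
  q_res <- sum(w * resid^2)
  infl <- max(1, sqrt(q_res / (J - K)))
  se_unit <- sqrt(diag(xtwx_inv))
  se <- se_unit * infl
  n_per <- attr(design, "n_snp_per_exposure")
  res <- lapply(seq_len(K), function(k) {
    mr_estimate("mvmr_ivw", beta[k], se[k], two_sided_p(beta[k] / se[k]),
                n_snp = unname(n_per[ids[k]]),
                exposure = ids[k], j_total = J, q_res = q_res,
                q_res_df = J - K)
  })
  names(res) <- ids
  res
}

#' Tidy MVMR results into a reporting table
#'
#' One row per exposure mirroring the conventional adjusted-estimate
#' layout: exposure, outcome, SNP count, p, OR with 95% CI (3 decimals).
#'
#' @param fits result of [mvmr_ivw()].
#' @param outcome_id outcome label.
#' @return data.frame.
#' @export
mvmr_table <- function(fits, outcome_id = NA_character_) {
  do.call(rbind, lapply(fits, function(e) {
    data.frame(exposure = e$exposure, outcome = outcome_id, n_snp = e$n_snp,
               pval = e$pval, beta = e$beta, se = e$se,
               OR = round(e$or, 3), CI_low = round(e$ci_low, 3),
               CI_high = round(e$ci_high, 3), stringsAsFactors = FALSE)
  }))
}
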
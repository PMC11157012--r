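# Heterogeneity, pleiotropy, outlier and influence diagnostics, plus the
# adjudication rule deciding which estimate a screen should trust.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (r_j - beta_fixed)^2)` over the per-SNP ratio estimates,
#' with first-order weights and the fixed-effect IVW center; J - 1 degrees
#' of freedom, upper chi-square tail p. Q = 0 iff all ratio estimates are
#' equal; p > 0.05 is read as no heterogeneity.
#'
#' @param hset a `harmonized_set` with J >= 2.
#' @return list `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(hset) {
  J <- nrow(hset)
  if (J < 2L) {
    mr_stop("mr_insufficient_instruments",
            "Cochran's Q needs at least 2 instruments")
  }
  rc <- ratio_components(hset)
  b_fixed <- sum(rc$w * rc$r) / sum(rc$w)
  q <- sum(rc$w * (rc$r - b_fixed)^2)
  list(q_stat = q, q_df = J - 1L,
       q_pval = max(stats::pchisq(q, J - 1L, lower.tail = FALSE),
                    .Machine$double.xmin))
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' Re-exports the intercept triple from [mr_egger()]; a p below 0.05 flags
#' directional pleiotropy. Needs J >= 3 (with 2 SNPs the regression cannot
#' be performed).
#'
#' @param hset a `harmonized_set` with J >= 3.
#' @return list `intercept`, `intercept_se`, `intercept_pval`,
#'   `pleiotropy_flag`.
#' @export
egger_intercept_test <- function(hset) {
  e <- mr_egger(hset)
  list(intercept = e$intercept, intercept_se = e$intercept_se,
       intercept_pval = e$intercept_pval,
       pleiotropy_flag = e$intercept_pval < 0.05)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate J times, excluding each SNP in turn, and
#' flags exclusions that change the sign of the estimate or move its p
#' across 0.05 relative to the full-set estimate.
#'
#' @param hset a `harmonized_set` with J >= 2.
#' @param model IVW model passed to [mr_ivw()].
#' @return data.frame with one row per excluded SNP (`excluded`, `beta`,
#'   `se`, `pval`, `sign_change`, `crosses_0.05`); the full-set estimate is
#'   attached as attribute `full`.
#' @export
leave_one_out <- function(hset, model = "multiplicative_random") {
  J <- nrow(hset)
  if (J < 2L) {
    mr_stop("mr_insufficient_instruments",
            "leave-one-out needs at least 2 instruments")
  }
  full <- mr_ivw(hset, model = model)
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(hset[-j, , drop = FALSE], model = model)
    data.frame(
      excluded = hset$variant_id[j], beta = e$beta, se = e$se,
      pval = e$pval,
      sign_change = sign(e$beta) != sign(full$beta),
      crosses_0.05 = (e$pval < 0.05) != (full$pval < 0.05),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

# leave-one-out fixed-effect IVW slopes, vectorized (PRESSO inner loop);
# works on matrices where rows are simulation replicates.
loo_slopes <- function(be, bo, se_out) {
  if (is.matrix(be)) {
    w <- sweep(be^2, 2, se_out^2, "/")
    r <- bo / be
    s1 <- rowSums(w * r)
    s0 <- rowSums(w)
    (s1 - w * r) / (s0 - w)
  } else {
    w <- be^2 / se_out^2
    r <- bo / be
    (sum(w * r) - w * r) / (sum(w) - w)
  }
}

#' MR-PRESSO: residual sum of squares and outlier test
#'
#' Global test: the observed statistic is
#' `RSS = sum_j (beta_out_j - b_(-j) beta_exp_j)^2 / se_out_j^2`, where
#' `b_(-j)` is the leave-one-out fixed-effect IVW slope. Its null
#' distribution is built from `n_sim` parametric replicates drawing
#' `beta_exp*_j ~ N(beta_exp_j, se_exp_j)` and
#' `beta_out*_j ~ N(b_(-j) beta_exp_j, se_out_j)` and recomputing the same
#' statistic; the global p is the fraction of simulated RSS at or above the
#' observed. Outlier test: the per-SNP p is the fraction of simulated j-th
#' squared residuals at or above the observed one, declared an outlier
#' below the Bonferroni bound `outlier_alpha / J`. When outliers are found
#' the IVW estimate is recomputed on the outlier-free set, and an
#' informational distortion test compares the raw-vs-corrected shift with a
#' null built by removing random SNP subsets of the same size.
#'
#' @param hset a `harmonized_set` with J >= 4.
#' @param n_sim parametric simulations, default 1000.
#' @param seed integer seed (required).
#' @param outlier_alpha per-test level before Bonferroni, default 0.05.
#' @param model IVW model for the corrected estimate.
#' @return A list of class `presso_result`: `global_rss_obs`,
#'   `global_pval`, `outlier_ids`, `outlier_pvals`, `corrected_ivw` (NULL
#'   when no outliers), `distortion_pval` (NULL when no outliers), `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed, outlier_alpha = 0.05,
                      model = "multiplicative_random") {
  J <- nrow(hset)
  if (J < 4L) {
    mr_stop("mr_insufficient_instruments",
            "MR-PRESSO needs at least 4 instruments")
  }
  be <- hset$beta_exp
  bo <- hset$beta_out
  se_e <- hset$se_exp
  se_o <- hset$se_out

  b_loo <- loo_slopes(be, bo, se_o)
  resid2_obs <- (bo - b_loo * be)^2 / se_o^2
  rss_obs <- sum(resid2_obs)

  sim <- with_seed(seed, {
    be_star <- matrix(stats::rnorm(n_sim * J, mean = rep(be, each = n_sim),
                                   sd = rep(se_e, each = n_sim)),
                      nrow = n_sim)
    bo_star <- matrix(stats::rnorm(n_sim * J,
                                   mean = rep(b_loo * be, each = n_sim),
                                   sd = rep(se_o, each = n_sim)),
                      nrow = n_sim)
    b_loo_star <- loo_slopes(be_star, bo_star, se_o)
    res2 <- sweep((bo_star - b_loo_star * be_star)^2, 2, se_o^2, "/")
    list(res2 = res2, rss = rowSums(res2))
  })

  global_pval <- mean(sim$rss >= rss_obs)
  outlier_pvals <- colMeans(sweep(sim$res2, 2, resid2_obs, ">="))
  names(outlier_pvals) <- hset$variant_id
  is_out <- outlier_pvals < outlier_alpha / J
  outlier_ids <- hset$variant_id[is_out]

  corrected <- NULL
  distortion_pval <- NULL
  if (length(outlier_ids)) {
    keep <- !is_out
    if (sum(keep) < 1L) {
      mr_stop("mr_empty_set", "all instruments flagged as outliers")
    }
    corrected <- mr_ivw(hset[keep, , drop = FALSE], model = model)
    raw <- mr_ivw(hset, model = model)
    d_obs <- raw$beta - corrected$beta
    k <- length(outlier_ids)
    distortion_pval <- with_seed(seed + 1L, {
      d_null <- replicate(500, {
        drop <- sample.int(J, k)
        raw$beta - mr_ivw(hset[-drop, , drop = FALSE], model = model)$beta
      })
      mean(abs(d_null) >= abs(d_obs))
    })
  }
  structure(
    list(global_rss_obs = rss_obs, global_pval = global_pval,
         outlier_ids = outlier_ids, outlier_pvals = outlier_pvals,
         corrected_ivw = corrected, distortion_pval = distortion_pval,
         n_sim = n_sim, seed = seed),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> RSS=%.2f global p=%.3g outliers=%d\n",
              x$global_rss_obs, x$global_pval, length(x$outlier_ids)))
  invisible(x)
}

#' Adjudicate which estimate a screen should trust
#'
#' Encodes the reporting rule used for summary-level MR screens: with a
#' single instrument only the Wald ratio exists and no sensitivity analysis
#' is possible (`wald_only`); with two instruments IVW and Q are available
#' but the Egger intercept is not, so pleiotropy is `not_assessable`; with
#' three or more, heterogeneity (Q p < 0.05) demotes IVW and promotes the
#' weighted median to primary (`wm_primary`) -- the causal claim then
#' stands only if the weighted median agrees in sign and remains
#' significant -- otherwise IVW stays primary (`ivw_primary`).
#'
#' @param ivw_est the IVW (or, at J = 1, Wald ratio) `mr_estimate`.
#' @param wm_est weighted-median `mr_estimate`, or NULL when J < 3.
#' @param q result of [cochran_q()], or NULL when J < 2.
#' @param egger result of [egger_intercept_test()], or NULL when J < 3.
#' @param presso a `presso_result`, or NULL when J < 4.
#' @param loo a [leave_one_out()] table, or NULL.
#' @return A list of class `sensitivity_report`: Q triple, Egger intercept
#'   p, presso, loo, `adjudication` (one of `ivw_primary`, `wm_primary`,
#'   `wald_only`, `not_assessable`), `pleiotropy_status`,
#'   `heterogeneity_flag`, `pleiotropy_flag`, and `primary` (the trusted
#'   `mr_estimate`).
#' @export
adjudicate_robustness <- function(ivw_est, wm_est = NULL, q = NULL,
                                  egger = NULL, presso = NULL, loo = NULL) {
  J <- ivw_est$n_snp
  het_flag <- if (!is.null(q)) q$q_pval < 0.05 else NA
  pleio_flag <- if (!is.null(egger)) egger$intercept_pval < 0.05 else NA
  if (J == 1L) {
    adjudication <- "wald_only"
    pleiotropy_status <- "not_assessable"
    primary <- ivw_est
  } else if (J == 2L) {
    adjudication <- "ivw_primary"
    pleiotropy_status <- "not_assessable"
    primary <- ivw_est
  } else if (isTRUE(het_flag) && !is.null(wm_est)) {
    adjudication <- "wm_primary"
    pleiotropy_status <- "assessed"
    primary <- wm_est
  } else {
    adjudication <- "ivw_primary"
    pleiotropy_status <- if (is.null(egger)) "not_assessable" else "assessed"
    primary <- ivw_est
  }
  structure(
    list(
      q_stat = if (!is.null(q)) q$q_stat else NA_real_,
      q_df = if (!is.null(q)) q$q_df else NA_integer_,
      q_pval = if (!is.null(q)) q$q_pval else NA_real_,
      egger_intercept_pval = if (!is.null(egger)) egger$intercept_pval
      else NA_real_,
      presso = presso, loo = loo,
      adjudication = adjudication,
      pleiotropy_status = pleiotropy_status,
      heterogeneity_flag = het_flag,
      pleiotropy_flag = pleio_flag,
      primary = primary
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> Q=%.3g (df=%s, p=%.3g) egger_p=%.3g adj=%s\n",
    x$q_stat, as.character(x$q_df), x$q_pval, x$egger_intercept_pval,
    x$adjudication
  ))
  invisible(x)
}
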
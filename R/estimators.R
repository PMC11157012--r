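# Causal-effect estimators over a harmonized exposure-outcome set.
#
# Notation: per SNP j, (beta_exp_j, se_exp_j) and (beta_out_j, se_out_j) are
# the aligned association estimates; r_j = beta_out_j / beta_exp_j is the
# ratio estimate and w_j = beta_exp_j^2 / se_out_j^2 the first-order inverse
# variance weight. The IVW estimate is the w-weighted mean of the r_j --
# algebraically the 1/se_out^2-weighted through-origin regression of
# beta_out on beta_exp.

Z95 <- 1.96

#' Construct an MR estimate object
#'
#' @param method one of `"wald_ratio"`, `"ivw"`, `"mr_egger"`,
#'   `"weighted_median"`, `"mvmr_ivw"`.
#' @param beta,se log-scale causal estimate and standard error.
#' @param pval two-sided p-value.
#' @param n_snp number of instruments used.
#' @param ... extra fields (e.g. Egger intercept triple, exposure id).
#' @return A list of class `mr_estimate` with the estimate, its odds-ratio
#'   transform `or`/`ci_low`/`ci_high` (95% CI, z = 1.96), and `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, pval, n_snp, ...) {
  or <- to_odds_ratio(beta, se)
  structure(
    c(list(method = method, beta = beta, se = se, pval = pval,
           or = or[["or"]], ci_low = or[["ci_low"]],
           ci_high = or[["ci_high"]], n_snp = n_snp),
      list(...)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta=%.4f se=%.4f p=%.3g OR=%.3f (%.3f-%.3f) J=%d\n",
    x$method, x$beta, x$se, x$pval, x$or, x$ci_low, x$ci_high, x$n_snp
  ))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept=%.4f se=%.4f p=%.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' Odds-ratio transform of a log-scale estimate
#'
#' `exp(beta)` with the 95% Wald interval `exp(beta -/+ 1.96 se)`. Values
#' are returned at full precision; report writers round to 3 decimals.
#'
#' @param beta log-scale effect.
#' @param se positive standard error.
#' @return named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(se > 0)
  c(or = exp(beta), ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se))
}

# ratio estimates and first-order weights for a harmonized set
ratio_components <- function(hset) {
  list(r = hset$beta_out / hset$beta_exp,
       w = hset$beta_exp^2 / hset$se_out^2)
}

#' Wald ratio (single-SNP) estimate
#'
#' `beta = beta_out / beta_exp`, first-order `se = se_out / |beta_exp|`,
#' two-sided normal p.
#'
#' @param hset a `harmonized_set` with exactly one row (a single SNP).
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(hset) {
  if (nrow(hset) != 1L) {
    mr_stop("mr_config_error", "wald ratio is a single-SNP estimator")
  }
  if (hset$beta_exp == 0) {
    mr_stop("mr_undefined_ratio", "exposure beta is zero; ratio undefined")
  }
  beta <- hset$beta_out / hset$beta_exp
  se <- hset$se_out / abs(hset$beta_exp)
  mr_estimate("wald_ratio", beta, se, two_sided_p(beta / se), 1L)
}

#' Inverse-variance weighted estimate
#'
#' First-order IVW: `beta = sum(w r) / sum(w)` with
#' `w = beta_exp^2 / se_out^2`. Fixed-effect `se = 1/sqrt(sum(w))`; the
#' default multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(J-1)))` (never deflates), where Q is Cochran's
#' fixed-effect heterogeneity statistic. p is two-sided normal. With J = 1
#' the estimate reduces exactly to the Wald ratio.
#'
#' @param hset a `harmonized_set`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"` (carries `q_stat`, `q_df`,
#'   `q_pval` for J >= 2).
#' @export
mr_ivw <- function(hset, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  J <- nrow(hset)
  if (J == 0L) mr_stop("mr_empty_set", "no instruments for IVW")
  if (any(hset$beta_exp == 0)) {
    mr_stop("mr_undefined_ratio", "exposure beta of zero in instrument set")
  }
  rc <- ratio_components(hset)
  beta <- sum(rc$w * rc$r) / sum(rc$w)
  se_fixed <- 1 / sqrt(sum(rc$w))
  q_stat <- sum(rc$w * (rc$r - beta)^2)
  if (J >= 2L) {
    q_df <- J - 1L
    q_pval <- stats::pchisq(q_stat, q_df, lower.tail = FALSE)
    infl <- if (model == "multiplicative_random") {
      max(1, sqrt(q_stat / q_df))
    } else 1
  } else {
    q_df <- NA_integer_
    q_pval <- NA_real_
    infl <- 1
  }
  se <- se_fixed * infl
  mr_estimate("ivw", beta, se, two_sided_p(beta / se), J,
              model = model, se_fixed = se_fixed,
              q_stat = q_stat, q_df = q_df, q_pval = q_pval)
}

#' MR-Egger regression
#'
#' Rows are first oriented so every exposure beta is non-negative (both
#' betas negated where needed; the estimate is invariant to per-SNP sign
#' flips). Then `beta_out` is regressed on `beta_exp` with an intercept and
#' weights `1/se_out^2`. The slope estimates the causal effect under the
#' InSIDE assumption; the intercept estimates the average directional
#' pleiotropic effect. Standard errors use the multiplicative
#' random-effects convention: the unit-residual-variance SEs inflated by
#' `max(1, residual standard deviation)`. p-values use t with J - 2 df.
#'
#' @param hset a `harmonized_set` with J >= 3 and non-constant exposure
#'   betas after orientation.
#' @return An `mr_estimate` with method `"mr_egger"` and fields
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(hset) {
  J <- nrow(hset)
  if (J < 3L) {
    mr_stop("mr_insufficient_instruments",
            "MR-Egger needs at least 3 instruments")
  }
  flip <- sign(hset$beta_exp)
  flip[flip == 0] <- 1
  x <- hset$beta_exp * flip
  y <- hset$beta_out * flip
  w <- 1 / hset$se_out^2
  if (stats::sd(x) == 0) {
    mr_stop("mr_singular_design",
            "all exposure betas equal after orientation; design is singular")
  }
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  est <- sm$coefficients[, "Estimate"]
  # lm's SEs already carry the residual sd; dividing by min(1, sigma)
  # keeps the inflation when sigma > 1 and removes the deflation otherwise.
  se <- sm$coefficients[, "Std. Error"] / min(1, sigma)
  df <- J - 2L
  pv <- two_sided_p_t(est / se, df)
  mr_estimate("mr_egger", unname(est["x"]), unname(se["x"]),
              unname(pv["x"]), J,
              intercept = unname(est["(Intercept)"]),
              intercept_se = unname(se["(Intercept)"]),
              intercept_pval = unname(pv["(Intercept)"]),
              residual_sd = sigma)
}

# interpolated weighted percentile of ratio estimates (the estimator core,
# shared with the bootstrap)
weighted_percentile <- function(r, w, q = 0.5) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (q <= s[1]) return(r[1])
  if (q >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = q, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Orders the ratio estimates, forms normalized cumulative weights
#' `s_j = (sum_{k<=j} w_k - w_j/2) / sum(w)` with `w = beta_exp^2/se_out^2`,
#' and interpolates the ratio at s = 0.5. Consistent when up to 50% of the
#' instrument weight comes from invalid instruments. The SE comes from a
#' seeded parametric bootstrap: exposure and outcome betas are resampled
#' from normals with their standard errors, the estimate recomputed, and
#' the standard deviation over replicates taken. p is two-sided normal.
#'
#' @param hset a `harmonized_set` with J >= 3.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed (required; results are bit-reproducible).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed) {
  J <- nrow(hset)
  if (J < 3L) {
    mr_stop("mr_insufficient_instruments",
            "weighted median needs at least 3 instruments")
  }
  rc <- ratio_components(hset)
  beta <- weighted_percentile(rc$r, rc$w, 0.5)
  boots <- with_seed(seed, {
    be <- matrix(stats::rnorm(n_boot * J, mean = rep(hset$beta_exp,
                                                     each = n_boot),
                              sd = rep(hset$se_exp, each = n_boot)),
                 nrow = n_boot)
    bo <- matrix(stats::rnorm(n_boot * J, mean = rep(hset$beta_out,
                                                     each = n_boot),
                              sd = rep(hset$se_out, each = n_boot)),
                 nrow = n_boot)
    vapply(seq_len(n_boot), function(i) {
      weighted_percentile(bo[i, ] / be[i, ], be[i, ]^2 / hset$se_out^2, 0.5)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, two_sided_p(beta / se), J,
              n_boot = n_boot, seed = seed)
}

#' Tidy one or more MR estimates into a reporting table
#'
#' One row per estimate: exposure, outcome, method, n_snp, log-scale beta
#' and se at full precision, p, and the odds ratio with 95% CI rounded to 3
#' decimals (the conventional reporting format).
#'
#' @param estimates an `mr_estimate` or list of them.
#' @param exposure_id,outcome_id trait labels for the table.
#' @return data.frame.
#' @export
mr_estimates_table <- function(estimates, exposure_id = NA_character_,
                               outcome_id = NA_character_) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(
      exposure = exposure_id, outcome = outcome_id, method = e$method,
      n_snp = e$n_snp, beta = e$beta, se = e$se, pval = e$pval,
      OR = round(e$or, 3), CI_low = round(e$ci_low, 3),
      CI_high = round(e$ci_high, 3), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
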
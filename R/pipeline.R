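# Orchestration: the exposure x outcome screen, multiple-testing
# classification, and the two-step mediation stage.

#' Bonferroni-corrected significance threshold
#'
#' `alpha / (n_exposures * n_outcomes)`. Returned at full precision;
#' reports print it at 3 significant figures but comparisons always use
#' the full-precision value (avoids boundary artifacts from rounding).
#'
#' @param n_exposures,n_outcomes positive counts of tested traits.
#' @param alpha family-wise level, default 0.05.
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  if (n_exposures < 1 || n_outcomes < 1) {
    mr_stop("mr_config_error", "counts must be >= 1")
  }
  alpha / (n_exposures * n_outcomes)
}

#' Classify an association against the corrected threshold
#'
#' `p < threshold` is `"significant"`, `threshold <= p < 0.05`
#' `"suggestive"`, anything else `"null"`. Vectorized over `p`.
#'
#' @param p p-value(s) in (0, 1].
#' @param threshold Bonferroni-corrected threshold (at most 0.05; the
#'   suggestive band is empty when it equals 0.05).
#' @return character vector of classifications.
#' @export
classify_association <- function(p, threshold) {
  if (threshold > 0.05) {
    mr_stop("mr_config_error", "threshold must not exceed the 0.05 band")
  }
  ifelse(p < threshold, "significant",
         ifelse(p < 0.05, "suggestive", "null"))
}

#' Screen configuration
#'
#' Bundles the selection thresholds and Monte-Carlo settings used by
#' [run_screen()] and [run_mediation_stage()].
#'
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param r2_max,window_kb LD clumping parameters.
#' @param maf_min MAF exclusion bound.
#' @param f_threshold weak-instrument bound.
#' @param exclusion_list variant ids to drop at harmonization.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim_presso MR-PRESSO simulations.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param n_tests override for the number of tests (defaults to
#'   exposures x outcomes of the screen at hand).
#' @param seed integer seed; mandatory (drives the weighted median and
#'   PRESSO; each pair uses an offset sub-seed).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 5e-8, r2_max = 0.001,
                          window_kb = 10000, maf_min = 0.01,
                          f_threshold = 10,
                          exclusion_list = character(),
                          n_boot = 1000, n_sim_presso = 1000,
                          alpha = 0.05, n_tests = NULL, seed) {
  if (missing(seed)) mr_stop("mr_config_error", "`seed` is mandatory")
  structure(
    list(p_threshold = p_threshold, r2_max = r2_max, window_kb = window_kb,
         maf_min = maf_min, f_threshold = f_threshold,
         exclusion_list = exclusion_list, n_boot = n_boot,
         n_sim_presso = n_sim_presso, alpha = alpha, n_tests = n_tests,
         seed = as.integer(seed)),
    class = "screen_config"
  )
}

# instrument selection for one exposure; returns the instrument_set plus an
# attrition record
select_instruments <- function(exposure, ld, config, quiet = TRUE) {
  attrition <- c(input = n_variants(exposure))
  s <- select_by_pvalue(exposure, config$p_threshold)
  attrition["genome_wide"] <- n_variants(s)
  if (!is.null(ld) && n_variants(s) > 1) {
    s <- ld_clump(s, ld, r2_max = config$r2_max,
                  window_kb = config$window_kb)
  }
  attrition["after_clump"] <- n_variants(s)
  s <- filter_maf_and_palindromes(s, maf_min = config$maf_min)
  attrition["after_maf_palindrome"] <- n_variants(s)
  inst <- compute_f_statistics(s, f_threshold = config$f_threshold,
                               quiet = quiet)
  attrition["after_f"] <- nrow(inst)
  list(instruments = inst, attrition = attrition)
}

# estimates + sensitivity for one harmonized set, dispatching on J
analyse_pair <- function(hset, config, pair_seed) {
  J <- nrow(hset)
  estimates <- list()
  q <- NULL; egger <- NULL; wm <- NULL; presso <- NULL; loo <- NULL
  if (J == 1L) {
    estimates$wald_ratio <- mr_wald_ratio(hset)
    report <- adjudicate_robustness(estimates$wald_ratio)
  } else {
    estimates$ivw <- mr_ivw(hset)
    q <- cochran_q(hset)
    loo <- leave_one_out(hset)
    if (J >= 3L) {
      # a singular Egger design (constant exposure betas) drops the Egger
      # column rather than aborting the whole pair
      eg <- tryCatch(mr_egger(hset),
                     mr_singular_design = function(e) NULL)
      if (!is.null(eg)) {
        estimates$mr_egger <- eg
        egger <- list(intercept = eg$intercept,
                      intercept_se = eg$intercept_se,
                      intercept_pval = eg$intercept_pval,
                      pleiotropy_flag = eg$intercept_pval < 0.05)
      }
      wm <- mr_weighted_median(hset, n_boot = config$n_boot,
                               seed = pair_seed)
      estimates$weighted_median <- wm
    }
    if (J >= 4L) {
      presso <- mr_presso(hset, n_sim = config$n_sim_presso,
                          seed = pair_seed + 1L)
    }
    report <- adjudicate_robustness(estimates$ivw, wm_est = wm, q = q,
                                    egger = egger, presso = presso,
                                    loo = loo)
  }
  list(estimates = estimates, sensitivity = report)
}

#' Run the exposure x outcome screen
#'
#' For every exposure-outcome pair: instrument selection, harmonization,
#' method dispatch by instrument count (J = 1 Wald ratio only; J = 2 IVW
#' with Cochran's Q; J >= 3 adds MR-Egger and the weighted median; J >= 4
#' adds MR-PRESSO), sensitivity adjudication, and classification of the
#' adjudicated primary p-value against the Bonferroni threshold. A pair
#' with no usable instruments -- or a single instrument, where no
#' sensitivity analysis can back the claim -- is recorded as
#' `not_established`, never a crash; so is a pair whose heterogeneity
#' demotes IVW and whose weighted median does not hold up (p >= 0.05 or
#' discordant sign).
#'
#' @param exposures,outcomes lists of `summary_stats` (single objects are
#'   wrapped).
#' @param ld an `ld_info` covering the exposure variants, or NULL to skip
#'   clumping.
#' @param config a `screen_config`.
#' @param quiet suppress per-pair progress messages.
#' @return list of `screen_result` objects (one per pair), each with
#'   `exposure_id`, `outcome_id`, `estimates`, `sensitivity`,
#'   `classification`, `n_snp_used`, `attrition`, `threshold`.
#' @export
run_screen <- function(exposures, outcomes, ld = NULL, config,
                       quiet = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  if (inherits(outcomes, "summary_stats")) outcomes <- list(outcomes)
  n_tests <- config$n_tests %||% (length(exposures) * length(outcomes))
  threshold <- bonferroni_threshold(n_tests, 1, alpha = config$alpha)
  results <- list()
  pair_idx <- 0L
  for (exposure in exposures) {
    sel <- tryCatch(select_instruments(exposure, ld, config),
                    mr_error = function(e) e)
    for (outcome in outcomes) {
      pair_idx <- pair_idx + 1L
      pair_seed <- config$seed + 10L * pair_idx
      res <- screen_one_pair(exposure, outcome, sel, config, pair_seed,
                             threshold, quiet = quiet)
      results[[paste0(exposure$trait_id, ".", outcome$trait_id)]] <- res
    }
  }
  structure(results, threshold = threshold, class = "screen_results")
}

screen_one_pair <- function(exposure, outcome, sel, config, pair_seed,
                            threshold, quiet = FALSE) {
  not_est <- function(attrition, why) {
    if (!quiet) {
      message("screen[", exposure$trait_id, " -> ", outcome$trait_id,
              "]: not established (", why, ")")
    }
    structure(
      list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
           estimates = list(), sensitivity = NULL,
           classification = "not_established", n_snp_used = 0L,
           attrition = attrition, threshold = threshold, note = why),
      class = "screen_result"
    )
  }
  if (inherits(sel, "condition")) {
    return(not_est(c(input = n_variants(exposure)), conditionMessage(sel)))
  }
  if (nrow(sel$instruments) == 0L) {
    return(not_est(sel$attrition, "no instruments survive selection"))
  }
  hset <- tryCatch(
    harmonize(sel$instruments, outcome,
              exclusion_list = config$exclusion_list, quiet = TRUE),
    mr_error = function(e) e
  )
  if (inherits(hset, "condition")) {
    return(not_est(sel$attrition, conditionMessage(hset)))
  }
  attrition <- c(sel$attrition, harmonized = nrow(hset))
  ana <- analyse_pair(hset, config, pair_seed)
  report <- ana$sensitivity
  primary <- report$primary
  classification <- unname(classify_association(primary$pval, threshold))
  if (report$adjudication == "wald_only") {
    # a single instrument cannot support a causal claim on its own
    classification <- "not_established"
  } else if (report$adjudication == "wm_primary") {
    ivw_beta <- ana$estimates$ivw$beta
    if (primary$pval >= 0.05 || sign(primary$beta) != sign(ivw_beta)) {
      classification <- "not_established"
    }
  }
  if (!quiet) {
    message("screen[", exposure$trait_id, " -> ", outcome$trait_id,
            "]: J=", nrow(hset), " primary=", primary$method,
            " p=", signif(primary$pval, 3), " -> ", classification)
  }
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         estimates = ana$estimates, sensitivity = report,
         classification = classification, n_snp_used = nrow(hset),
         attrition = attrition, threshold = threshold, note = NA_character_),
    class = "screen_result"
  )
}

#' Tidy screen results into a reporting table
#'
#' One row per estimate per pair, with the heterogeneity and
#' Egger-intercept p-values, the adjudication and the classification --
#' the layout of a conventional two-sample MR results table.
#'
#' @param results a `screen_results` list from [run_screen()].
#' @return data.frame.
#' @export
screen_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (!length(r$estimates)) {
      return(data.frame(
        exposure = r$exposure_id, outcome = r$outcome_id,
        method = NA_character_, n_snp = 0L, beta = NA_real_, se = NA_real_,
        pval = NA_real_, OR = NA_real_, CI_low = NA_real_,
        CI_high = NA_real_, q_pval = NA_real_, egger_intercept_pval = NA_real_,
        adjudication = "not_assessable", classification = r$classification,
        stringsAsFactors = FALSE
      ))
    }
    tab <- mr_estimates_table(unname(r$estimates), r$exposure_id,
                              r$outcome_id)
    tab$q_pval <- r$sensitivity$q_pval
    tab$egger_intercept_pval <- r$sensitivity$egger_intercept_pval
    tab$adjudication <- r$sensitivity$adjudication
    tab$classification <- r$classification
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a screen results table to TSV
#' @param results a `screen_results` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(results, path) {
  utils::write.table(screen_results_table(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the two-step mediation stage
#'
#' For one exposure, a set of candidate mediators and a set of outcomes:
#' beta1 comes from the exposure -> outcome screen (the adjudicated
#' primary), beta2 from an exposure -> mediator MR, and beta3 from a
#' mediator -> outcome MR whose instrument set excludes the exposure's own
#' instruments (so the mediator's instruments are not downstream of the
#' exposure). A triplet whose mediator -> outcome link is not established
#' (adjudication withdraws it, or its primary p >= 0.05) is emitted with a
#' `not_established` flag and no proportion rather than dropped.
#'
#' @param exposure a `summary_stats`.
#' @param mediators,outcomes lists of `summary_stats` (single objects are
#'   wrapped).
#' @param ld optional `ld_info` (shared variant universe), or NULL.
#' @param config a `screen_config`.
#' @param profile rounding profile for the assembled table.
#' @param quiet passed through.
#' @return list with `table` (the [mediation_table()] output), `beta1`,
#'   `beta2`, `beta3` component estimate tables.
#' @export
run_mediation_stage <- function(exposure, mediators, outcomes, ld = NULL,
                                config,
                                profile = c("full_precision",
                                            "published_rounding"),
                                quiet = TRUE) {
  profile <- match.arg(profile)
  stopifnot(inherits(config, "screen_config"))
  if (inherits(mediators, "summary_stats")) mediators <- list(mediators)
  if (inherits(outcomes, "summary_stats")) outcomes <- list(outcomes)

  # step 0: total effects beta1 (exposure -> outcome)
  scr1 <- run_screen(exposure, outcomes, ld = ld, config = config,
                     quiet = quiet)
  # step 1: exposure -> mediator (beta2)
  scr2 <- run_screen(exposure, mediators, ld = ld, config = config,
                     quiet = quiet)
  # step 2: mediator -> outcome (beta3), excluding exposure instruments
  exp_inst <- tryCatch(
    select_instruments(exposure, ld, config)$instruments$variant_id,
    mr_error = function(e) character(0)
  )
  config3 <- config
  config3$exclusion_list <- union(config$exclusion_list, exp_inst)
  scr3 <- run_screen(mediators, outcomes, ld = ld, config = config3,
                     quiet = quiet)

  grab <- function(scr, exp_id, out_id) {
    r <- scr[[paste0(exp_id, ".", out_id)]]
    if (is.null(r) || !length(r$estimates)) return(NULL)
    list(est = r$sensitivity$primary, classification = r$classification)
  }
  triplets <- NULL
  for (med in mediators) {
    for (out in outcomes) {
      b1 <- grab(scr1, exposure$trait_id, out$trait_id)
      b2 <- grab(scr2, exposure$trait_id, med$trait_id)
      b3 <- grab(scr3, med$trait_id, out$trait_id)
      established <- !is.null(b3) && b3$classification != "not_established" &&
        b3$est$pval < 0.05
      triplets <- rbind(triplets, data.frame(
        exposure = exposure$trait_id, mediator = med$trait_id,
        outcome = out$trait_id,
        beta1 = if (!is.null(b1)) b1$est$beta else NA_real_,
        beta2 = if (!is.null(b2)) b2$est$beta else NA_real_,
        beta3 = if (!is.null(b3) && established) b3$est$beta else NA_real_,
        established = established, stringsAsFactors = FALSE
      ))
    }
  }
  list(table = mediation_table(triplets, profile = profile),
       beta1 = scr1, beta2 = scr2, beta3 = scr3)
}
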
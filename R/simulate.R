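# Synthetic GWAS summary statistics under a fully specified causal model.
#
# Per variant j with effect-allele frequency p_j, the sampling SE of an
# association estimate in a GWAS of n individuals on a standardized trait
# is se_j = 1 / sqrt(2 n p_j (1 - p_j)); binary traits are simulated on the
# log-odds scale with the same normal approximation and n read as an
# effective sample size. True SNP-exposure effects gamma_j are drawn as
# |N(0, gamma_sd)|, floored in magnitude so instruments clear genome-wide
# significance at the exposure sample size, and the generator reports the
# exposure-increasing allele as the effect allele -- the orientation in
# which "directional" pleiotropy is meaningful (with sign-symmetric
# instrument effects, a constant pleiotropic shift is indistinguishable
# from balanced pleiotropy once MR-Egger orients its rows). The true
# outcome effect is causal_beta * gamma_j + alpha_j (+ an outlier bump for
# flagged SNPs); observed betas are drawn from normals around the truths.

GW_SIG_Z <- stats::qnorm(2.5e-9, lower.tail = FALSE)  # z for p = 5e-8

#' Simulation configuration
#'
#' @param n_snps number of exposure instruments.
#' @param causal_beta true exposure -> outcome effect.
#' @param n_exp,n_out,n_med GWAS (effective) sample sizes.
#' @param gamma_sd sd of the half-normal true SNP-exposure effect
#'   distribution (default 0.05).
#' @param gamma_floor_margin instruments are floored at
#'   `(z_{5e-8} + margin) * se_exp_j` so each clears genome-wide
#'   significance with high probability; default margin 2 (~98% per SNP).
#' @param pleiotropy list with `mode` (`"none"`, `"balanced"`,
#'   `"directional"`, `"inside_violating"`), `mu_alpha`, `sigma_alpha`,
#'   `rho` (copula correlation with instrument strength, used by
#'   `inside_violating`), and `prop_invalid` (fraction of SNPs receiving a
#'   pleiotropic effect; default 1).
#' @param mediator_spec NULL, or list `beta2_true` (exposure -> mediator),
#'   `beta3_true` (mediator -> outcome), `direct_beta` (exposure -> outcome
#'   not through the mediator), `n_mediator_snps` (mediator-specific
#'   instruments; default `n_snps`).
#' @param eaf_range effect-allele frequency range, default `c(0.05, 0.95)`.
#' @param n_outliers SNPs given an outlier bump on the outcome effect.
#' @param outlier_scale bump size in units of the outcome SE (default 10;
#'   applied with positive sign -- see the methods vignette).
#' @param ld_blocks NULL (independent SNPs), or list `block_size`, `r2`
#'   for block-diagonal LD with constant within-block r-squared.
#' @param seed integer seed; mandatory, every draw is derived from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_snps = 50, causal_beta = 0.2,
                              n_exp = 5e5, n_out = 5e5, n_med = 5e5,
                              gamma_sd = 0.05, gamma_floor_margin = 2,
                              pleiotropy = list(mode = "none"),
                              mediator_spec = NULL,
                              eaf_range = c(0.05, 0.95),
                              n_outliers = 0, outlier_scale = 10,
                              ld_blocks = NULL, seed) {
  if (missing(seed)) mr_stop("mr_config_error", "`seed` is mandatory")
  pl <- utils::modifyList(
    list(mode = "none", mu_alpha = 0, sigma_alpha = 0, rho = 0,
         prop_invalid = 1),
    pleiotropy
  )
  if (!pl$mode %in% c("none", "balanced", "directional", "inside_violating")) {
    mr_stop("mr_config_error", paste0("unknown pleiotropy mode: ", pl$mode))
  }
  if (pl$rho < -1 || pl$rho > 1) {
    mr_stop("mr_config_error", "rho must lie in [-1, 1]")
  }
  if (pl$prop_invalid < 0 || pl$prop_invalid > 1) {
    mr_stop("mr_config_error", "prop_invalid must lie in [0, 1]")
  }
  if (any(c(n_snps, n_exp, n_out, n_med) <= 0) || gamma_sd <= 0) {
    mr_stop("mr_config_error", "sizes and scales must be positive")
  }
  if (eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] >= eaf_range[2]) {
    mr_stop("mr_config_error", "eaf_range must be inside (0, 1), increasing")
  }
  if (!is.null(mediator_spec)) {
    need <- c("beta2_true", "beta3_true", "direct_beta")
    if (!all(need %in% names(mediator_spec))) {
      mr_stop("mr_config_error", paste0(
        "mediator_spec needs: ", paste(need, collapse = ", ")
      ))
    }
    mediator_spec$n_mediator_snps <- mediator_spec$n_mediator_snps %||% n_snps
  }
  if (!is.null(ld_blocks)) {
    if (is.null(ld_blocks$block_size) || is.null(ld_blocks$r2)) {
      mr_stop("mr_config_error", "ld_blocks needs `block_size` and `r2`")
    }
  }
  structure(
    list(n_snps = as.integer(n_snps), causal_beta = causal_beta,
         n_exp = n_exp, n_out = n_out, n_med = n_med,
         gamma_sd = gamma_sd, gamma_floor_margin = gamma_floor_margin,
         pleiotropy = pl, mediator_spec = mediator_spec,
         eaf_range = eaf_range, n_outliers = as.integer(n_outliers),
         outlier_scale = outlier_scale, ld_blocks = ld_blocks,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# standardized-trait sampling SE
gwas_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

# observed table for one trait from true effects
observed_table <- function(ids, ea, oa, eaf, true_beta, se, n, chrom, pos,
                           trait_id, effect_scale) {
  beta <- stats::rnorm(length(ids), mean = true_beta, sd = se)
  summary_stats(
    data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta, se = se,
               pval = two_sided_p(beta / se), n = n,
               chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    trait_id = trait_id, effect_scale = effect_scale, quiet = TRUE
  )
}

# pleiotropic effects for J SNPs given oriented instrument strengths gamma
draw_alpha <- function(pl, gamma) {
  J <- length(gamma)
  alpha <- numeric(J)
  n_inv <- round(pl$prop_invalid * J)
  if (pl$mode == "none" || n_inv == 0) return(alpha)
  inv <- sample.int(J, n_inv)
  g <- gamma[inv]
  eps <- stats::rnorm(n_inv)
  core <- switch(
    pl$mode,
    balanced = pl$sigma_alpha * eps,
    directional = pl$mu_alpha + pl$sigma_alpha * eps,
    inside_violating = {
      # Gaussian copula between |gamma| and alpha: rank-transform the
      # strengths to normal scores, mix with rho.
      z_g <- stats::qnorm(rank(g, ties.method = "average") / (n_inv + 1))
      pl$mu_alpha +
        pl$sigma_alpha * (pl$rho * z_g + sqrt(1 - pl$rho^2) * eps)
    }
  )
  alpha[inv] <- core
  alpha
}

# genomic layout and LD matrix: blocks sit on chromosome 1, spaced far
# beyond the clumping window; SNPs within a block are adjacent.
genome_layout <- function(J, ld_blocks) {
  if (is.null(ld_blocks)) {
    block <- seq_len(J)
  } else {
    block <- rep(seq_len(ceiling(J / ld_blocks$block_size)),
                 each = ld_blocks$block_size)[seq_len(J)]
  }
  pos <- block * 2e7 + stats::ave(seq_len(J), block, FUN = seq_along) * 1e4
  r2 <- diag(J)
  if (!is.null(ld_blocks)) {
    same <- outer(block, block, "==")
    r2[same] <- ld_blocks$r2
    diag(r2) <- 1
  }
  list(chrom = rep("1", J), pos = pos, r2 = r2, block = block)
}

#' Simulate an exposure-outcome GWAS pair
#'
#' Draws true per-SNP exposure effects, pleiotropic effects and outlier
#' bumps per the configuration, then emits observed exposure and outcome
#' summary-statistics tables with sampling noise scaled by sample size and
#' allele frequency, a pairwise LD object, and a truth record aligned
#' one-to-one with the emitted variants. Bit-reproducible from the seed.
#'
#' @param config a `sim_config`.
#' @return list with elements `exposure`, `outcome` (`summary_stats`),
#'   `ld` (`ld_info`), `truth` (data.frame: `variant_id`, `gamma`,
#'   `alpha`, `outlier`, `true_beta_out`, `f_true`), `config`.
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_gwas_pair_impl(config))
}

simulate_gwas_pair_impl <- function(config) {
  J <- config$n_snps
  eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
  se_e <- gwas_se(config$n_exp, eaf)
  se_o <- gwas_se(config$n_out, eaf)

  floor_j <- (GW_SIG_Z + config$gamma_floor_margin) * se_e
  if (stats::median(floor_j) > 4 * config$gamma_sd) {
    mr_stop("mr_feasibility_error", paste0(
      "instruments cannot plausibly reach genome-wide significance: the ",
      "significance floor (", signif(stats::median(floor_j), 3),
      ") dwarfs gamma_sd (", config$gamma_sd,
      "); increase n_exp or gamma_sd"
    ))
  }
  gamma <- pmax(abs(stats::rnorm(J, 0, config$gamma_sd)), floor_j)

  alpha <- draw_alpha(config$pleiotropy, gamma)
  outlier <- rep(FALSE, J)
  if (config$n_outliers > 0) {
    outlier[sample.int(J, min(config$n_outliers, J))] <- TRUE
  }
  bump <- ifelse(outlier, config$outlier_scale * se_o, 0)
  true_out <- config$causal_beta * gamma + alpha + bump

  ids <- sprintf("rs%06d", seq_len(J))
  # effect allele = exposure-increasing allele; pairs drawn non-palindromic
  ea <- sample(ALLELES, J, replace = TRUE)
  oa <- vapply(ea, function(a) {
    sample(setdiff(ALLELES, c(a, COMPLEMENT[[a]])), 1)
  }, character(1))
  lay <- genome_layout(J, config$ld_blocks)
  dimnames(lay$r2) <- list(ids, ids)

  exposure <- observed_table(ids, ea, oa, eaf, gamma, se_e, config$n_exp,
                             lay$chrom, lay$pos, "exposure", "sd_units")
  outcome <- observed_table(ids, ea, oa, eaf, true_out, se_o, config$n_out,
                            lay$chrom, lay$pos, "outcome", "log_odds")
  truth <- data.frame(
    variant_id = ids, gamma = gamma, alpha = alpha, outlier = outlier,
    true_beta_out = true_out, f_true = gamma^2 / se_e^2,
    stringsAsFactors = FALSE
  )
  list(exposure = exposure, outcome = outcome, ld = ld_info(lay$r2),
       truth = truth, config = config)
}

#' Simulate an exposure-mediator-outcome triplet
#'
#' Two disjoint instrument sets are emitted in the same tables: `n_snps`
#' exposure instruments (affecting the mediator through `beta2_true` and
#' the outcome through `direct_beta + beta2_true * beta3_true`) and
#' `n_mediator_snps` mediator-specific instruments (no exposure effect,
#' outcome effect `beta3_true * delta`). Pleiotropy and outliers, when
#' configured, apply to the exposure instruments' outcome effects. The
#' truth record carries the true total effect
#' `beta1 = direct_beta + beta2_true * beta3_true` and the true mediated
#' proportion.
#'
#' @param config a `sim_config` with `mediator_spec` present.
#' @return list `exposure`, `mediator`, `outcome` (`summary_stats`), `ld`,
#'   `truth` (with attribute-free columns plus `set` = "exposure" or
#'   "mediator"), `true_beta1`, `true_proportion`, `config`.
#' @export
simulate_mediation_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ms <- config$mediator_spec
  if (is.null(ms)) {
    mr_stop("mr_config_error", "mediator_spec is required for a triplet")
  }
  with_seed(config$seed, {
    JA <- config$n_snps
    JB <- ms$n_mediator_snps
    J <- JA + JB
    eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
    se_e <- gwas_se(config$n_exp, eaf)
    se_m <- gwas_se(config$n_med, eaf)
    se_o <- gwas_se(config$n_out, eaf)

    idxA <- seq_len(JA)
    idxB <- JA + seq_len(JB)
    floorA <- (GW_SIG_Z + config$gamma_floor_margin) * se_e[idxA]
    floorB <- (GW_SIG_Z + config$gamma_floor_margin) * se_m[idxB]
    if (stats::median(c(floorA, floorB)) > 4 * config$gamma_sd) {
      mr_stop("mr_feasibility_error",
              "instruments cannot plausibly reach genome-wide significance")
    }
    gamma <- pmax(abs(stats::rnorm(JA, 0, config$gamma_sd)), floorA)
    delta <- pmax(abs(stats::rnorm(JB, 0, config$gamma_sd)), floorB)

    alpha <- numeric(J)
    alpha[idxA] <- draw_alpha(config$pleiotropy, gamma)
    outlier <- rep(FALSE, J)
    if (config$n_outliers > 0) {
      outlier[sample(idxA, min(config$n_outliers, JA))] <- TRUE
    }
    bump <- ifelse(outlier, config$outlier_scale * se_o, 0)

    true_exp <- c(gamma, rep(0, JB))
    true_med <- c(ms$beta2_true * gamma, delta)
    true_out <- ms$direct_beta * true_exp + ms$beta3_true * true_med +
      alpha + bump

    ids <- sprintf("rs%06d", seq_len(J))
    ea <- sample(ALLELES, J, replace = TRUE)
    oa <- vapply(ea, function(a) {
      sample(setdiff(ALLELES, c(a, COMPLEMENT[[a]])), 1)
    }, character(1))
    lay <- genome_layout(J, config$ld_blocks)
    dimnames(lay$r2) <- list(ids, ids)

    exposure <- observed_table(ids, ea, oa, eaf, true_exp, se_e,
                               config$n_exp, lay$chrom, lay$pos,
                               "exposure", "sd_units")
    mediator <- observed_table(ids, ea, oa, eaf, true_med, se_m,
                               config$n_med, lay$chrom, lay$pos,
                               "mediator", "sd_units")
    outcome <- observed_table(ids, ea, oa, eaf, true_out, se_o,
                              config$n_out, lay$chrom, lay$pos,
                              "outcome", "log_odds")
    true_beta1 <- ms$direct_beta + ms$beta2_true * ms$beta3_true
    truth <- data.frame(
      variant_id = ids,
      set = c(rep("exposure", JA), rep("mediator", JB)),
      true_beta_exp = true_exp, true_beta_med = true_med,
      true_beta_out = true_out, alpha = alpha, outlier = outlier,
      stringsAsFactors = FALSE
    )
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = ld_info(lay$r2), truth = truth,
         true_beta1 = true_beta1,
         true_proportion = ms$beta2_true * ms$beta3_true / true_beta1,
         config = config)
  })
}

#' Named scenario presets
#'
#' Documented configurations exercising each pipeline stage:
#' \describe{
#'   \item{valid}{50 strong, valid instruments; no pleiotropy.}
#'   \item{balanced_pleio}{zero-mean pleiotropy, sd 0.05, on all SNPs.}
#'   \item{directional_pleio}{mean 0.05 (sd 0.02) pleiotropy on all SNPs,
#'     InSIDE respected (exercises the Egger intercept).}
#'   \item{inside_violation}{as directional but with copula correlation
#'     0.7 between pleiotropy and instrument strength.}
#'   \item{with_outliers}{2 of 50 SNPs with a 10x outcome-SE residual bump
#'     (exercises MR-PRESSO).}
#'   \item{weak_instruments}{no significance floor and small effects so
#'     roughly 30% of SNPs fall below F = 10 (exercises the F filter).}
#'   \item{mediation}{triplet with direct effect 0.15, beta2 0.25,
#'     beta3 0.2: true mediated proportion 0.25.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
scenario_presets <- function(name = c("valid", "balanced_pleio",
                                      "directional_pleio",
                                      "inside_violation", "with_outliers",
                                      "weak_instruments", "mediation"),
                             seed, ...) {
  if (length(name) != 1 || !name %in% c(
    "valid", "balanced_pleio", "directional_pleio", "inside_violation",
    "with_outliers", "weak_instruments", "mediation"
  )) {
    mr_stop("mr_config_error", paste0(
      "unknown scenario preset: ", paste(name, collapse = ", ")
    ))
  }
  args <- switch(
    name,
    valid = list(),
    balanced_pleio = list(
      pleiotropy = list(mode = "balanced", sigma_alpha = 0.05)
    ),
    directional_pleio = list(
      pleiotropy = list(mode = "directional", mu_alpha = 0.05,
                        sigma_alpha = 0.02)
    ),
    inside_violation = list(
      pleiotropy = list(mode = "inside_violating", mu_alpha = 0.05,
                        sigma_alpha = 0.02, rho = 0.7)
    ),
    with_outliers = list(n_outliers = 2, outlier_scale = 10),
    weak_instruments = list(gamma_sd = 0.02, gamma_floor_margin = -GW_SIG_Z),
    mediation = list(
      mediator_spec = list(beta2_true = 0.25, beta3_true = 0.2,
                           direct_beta = 0.15)
    )
  )
  do.call(simulation_config,
          utils::modifyList(c(args, list(seed = seed)), list(...)))
}
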
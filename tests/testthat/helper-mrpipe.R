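# Shared builders and independent oracles for the test suite.

# quick summary_stats from vectors; defaults give valid, non-palindromic rows
make_stats <- function(n = 3, trait_id = "trait",
                       variant_id = sprintf("rs%04d", seq_len(n)),
                       effect_allele = rep("A", n),
                       other_allele = rep("G", n),
                       eaf = rep(0.3, n),
                       beta = rep(0.1, n),
                       se = rep(0.01, n),
                       pval = NULL,
                       n_col = NA, chrom = NA, pos = NA, ...) {
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  summary_stats(
    data.frame(variant_id = variant_id, effect_allele = effect_allele,
               other_allele = other_allele, eaf = eaf, beta = beta,
               se = se, pval = pval, n = n_col, chrom = chrom, pos = pos,
               stringsAsFactors = FALSE),
    trait_id = trait_id, quiet = TRUE, ...
  )
}

make_hset <- function(beta_exp, se_exp, beta_out, se_out, ...) {
  harmonized_set(
    data.frame(beta_exp = beta_exp, se_exp = se_exp,
               beta_out = beta_out, se_out = se_out),
    ...
  )
}

# harmonized set straight from a simulated pair (truth-aligned; bypasses
# selection, which is exercised separately)
hset_from_sim <- function(sim) {
  harmonized_set(
    data.frame(variant_id = sim$truth$variant_id,
               beta_exp = sim$exposure$records$beta,
               se_exp = sim$exposure$records$se,
               beta_out = sim$outcome$records$beta,
               se_out = sim$outcome$records$se),
    exposure_id = "exposure", outcome_id = "outcome"
  )
}

# independent weighted-median oracle: explicit scan, no interpolation call
brute_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  J <- length(r)
  if (0.5 >= s[J]) return(r[J])
  below <- max(which(s < 0.5))
  if (s[below + 1] == 0.5) return(r[below + 1])
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

# independent greedy clumping oracle over explicit id/p/chrom/pos vectors
brute_clump <- function(ids, pval, chrom, pos, r2mat, r2_max, window_bp) {
  remaining <- order(pval)
  kept <- integer(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    remaining <- remaining[-1]
    drop <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      if (chrom[top] == chrom[j] && abs(pos[top] - pos[j]) < window_bp) {
        if (r2mat[ids[top], ids[j]] >= r2_max) drop[k] <- TRUE
      }
    }
    remaining <- remaining[!drop]
  }
  ids[kept]
}
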
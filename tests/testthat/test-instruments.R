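test_that("p-value selection is strict and matches a brute-force recount", {
  s <- make_stats(n = 2, pval = c(4e-8, 6e-8))
  expect_equal(select_by_pvalue(s)$records$variant_id, "rs0001")
  expect_equal(n_variants(select_by_pvalue(make_stats(n = 3, pval = rep(0.5, 3)))), 0L)
  set.seed(11)
  p <- runif(100)
  s <- make_stats(n = 100, pval = p)
  expect_equal(n_variants(select_by_pvalue(s, 0.3)), sum(p < 0.3))
  expect_error(select_by_pvalue(s, 1.5), class = "mr_config_error")
})

test_that("MAF and palindrome filters apply the stated conventions", {
  s <- make_stats(
    n = 4,
    effect_allele = c("A", "A", "A", "C"),
    other_allele = c("G", "T", "G", "G"),
    eaf = c(0.01, 0.30, 0.50, 0.99)
  )
  kept <- filter_maf_and_palindromes(s)
  # eaf 0.01 dropped (inclusive bound), A/T dropped (palindromic),
  # eaf 0.99 dropped (MAF = 0.01), A/G at 0.5 retained
  expect_equal(kept$records$variant_id, "rs0003")
  just_above <- filter_maf_and_palindromes(
    make_stats(n = 1, eaf = 0.0100001)
  )
  expect_equal(n_variants(just_above), 1L)
})

test_that("F-statistics follow beta^2/se^2 and gate at the threshold", {
  s <- make_stats(n = 3, beta = c(0.1, 0.03, -0.1),
                  se = c(0.02, 0.01, 0.02))
  inst <- compute_f_statistics(s, quiet = TRUE)
  # F = 25 retained (sign-invariant), F = 9 excluded
  expect_equal(inst$variant_id, c("rs0001", "rs0003"))
  expect_equal(inst$f_stat, c(25, 25))
  expect_equal(inst$f_stat, inst$beta_exp^2 / inst$se_exp^2,
               tolerance = 1e-9)
})

test_that("pairwise clumping keeps the more significant SNP and respects chromosomes", {
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("rs0001", "rs0002"),
                                                     c("rs0001", "rs0002")))
  ld <- ld_info(r2)
  s <- make_stats(n = 2, pval = c(1e-10, 1e-9), chrom = c("1", "1"),
                  pos = c(1e5, 2e5))
  expect_equal(ld_clump(s, ld)$records$variant_id, "rs0001")
  # different chromosomes: both kept even without an LD entry
  r2_diag <- diag(2); dimnames(r2_diag) <- dimnames(r2)
  s2 <- make_stats(n = 2, pval = c(1e-10, 1e-9), chrom = c("1", "2"),
                   pos = c(1e5, 1e5))
  expect_equal(n_variants(ld_clump(s2, ld_info(r2_diag))), 2L)
  # a missing pair inside the window is a hard error
  r2_na <- r2; r2_na[1, 2] <- r2_na[2, 1] <- NA
  expect_error(ld_clump(s, ld_info(r2_na)), class = "mr_missing_ld")
})

test_that("block-LD clumping equals an independent greedy oracle", {
  set.seed(21)
  sim <- simulate_gwas_pair(simulation_config(
    n_snps = 12, seed = 77, ld_blocks = list(block_size = 3, r2 = 0.4)
  ))
  s <- sim$exposure
  clumped <- ld_clump(s, sim$ld, r2_max = 0.2, window_kb = 10000)
  oracle <- brute_clump(
    s$records$variant_id, s$records$pval, s$records$chrom, s$records$pos,
    sim$ld$r2, r2_max = 0.2, window_bp = 1e7
  )
  expect_setequal(clumped$records$variant_id, oracle)
  # output ordered by ascending p
  expect_false(is.unsorted(clumped$records$pval))
})

test_that("LD files round-trip through both accepted layouts", {
  ids <- c("rs1", "rs2", "rs3")
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.7
  dimnames(r2) <- list(ids, ids)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(r2, mpath, sep = "\t", quote = FALSE)
  ld_m <- read_ld_file(mpath)
  expect_equal(ld_r2(ld_m, "rs1", "rs2"), 0.7)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rs1\trs2\t0.7", "rs1\trs3\t0"), ppath)
  ld_p <- read_ld_file(ppath)
  expect_equal(ld_r2(ld_p, "rs2", "rs1"), 0.7)
  expect_true(is.na(ld_r2(ld_p, "rs2", "rs3")))  # unlisted pair: missing
})

test_that("harmonization resolves every allele configuration per the truth table", {
  pairs <- expand.grid(ea = c("A", "C", "G", "T"), oa = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  pairs <- pairs[!(paste0(pairs$ea, pairs$oa) %in%
                     c("AT", "TA", "CG", "GC")), ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in seq_len(nrow(pairs))) {
    ea <- pairs$ea[i]; oa <- pairs$oa[i]
    cases <- list(
      same = list(out = c(ea, oa), kept = TRUE, sign = 1),
      swapped = list(out = c(oa, ea), kept = TRUE, sign = -1),
      comp_same = list(out = unname(c(comp[ea], comp[oa])), kept = TRUE,
                       sign = 1),
      comp_swap = list(out = unname(c(comp[oa], comp[ea])), kept = TRUE,
                       sign = -1),
      mismatch = list(out = c(ea, setdiff(c("A", "C", "G", "T"),
                                          c(ea, oa, comp[[ea]]))[1]),
                      kept = FALSE, sign = NA)
    )
    for (nm in names(cases)) {
      cs <- cases[[nm]]
      if (cs$out[1] == cs$out[2]) next  # degenerate outcome pair
      inst <- compute_f_statistics(
        make_stats(n = 1, effect_allele = ea, other_allele = oa,
                   beta = 0.1, se = 0.01, trait_id = "exp"),
        quiet = TRUE
      )
      out <- make_stats(n = 1, effect_allele = cs$out[1],
                        other_allele = cs$out[2], beta = 0.2, se = 0.05,
                        trait_id = "out")
      if (cs$kept) {
        h <- harmonize(inst, out, quiet = TRUE)
        expect_equal(nrow(h), 1L, info = paste(ea, oa, nm))
        expect_equal(h$beta_out, cs$sign * 0.2, info = paste(ea, oa, nm))
        expect_equal(h$effect_allele, ea)
      } else {
        expect_error(harmonize(inst, out, quiet = TRUE),
                     class = "mr_empty_set")
      }
    }
  }
})

test_that("harmonization drops exclusion-list SNPs and errors on empty intersections", {
  inst <- compute_f_statistics(make_stats(n = 3, trait_id = "exp"),
                               quiet = TRUE)
  out <- make_stats(n = 3, beta = rep(0.2, 3), se = rep(0.05, 3),
                    trait_id = "out")
  h <- harmonize(inst, out, exclusion_list = "rs0002", quiet = TRUE)
  expect_setequal(h$variant_id, c("rs0001", "rs0003"))
  expect_equal(attr(h, "attrition")[["excluded_by_list"]], 1L)
  out2 <- make_stats(n = 2, variant_id = c("rsX", "rsY"), trait_id = "out")
  expect_error(harmonize(inst, out2, quiet = TRUE), class = "mr_empty_set")
})

test_that("harmonization is involutive on an already-aligned set", {
  inst <- compute_f_statistics(
    make_stats(n = 4, beta = c(0.1, -0.12, 0.2, 0.15),
               effect_allele = c("A", "C", "G", "T"),
               other_allele = c("G", "A", "A", "C"), trait_id = "exp"),
    quiet = TRUE
  )
  out <- make_stats(n = 4, beta = c(0.05, 0.01, -0.04, 0.02),
                    se = rep(0.02, 4),
                    effect_allele = c("G", "C", "G", "T"),
                    other_allele = c("A", "A", "A", "C"),
                    trait_id = "out")
  h1 <- harmonize(inst, out, quiet = TRUE)
  # rebuild an outcome table from the harmonized rows and harmonize again
  out_aligned <- make_stats(
    n = nrow(h1), variant_id = h1$variant_id,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_out, beta = h1$beta_out, se = h1$se_out, trait_id = "out"
  )
  h2 <- harmonize(inst, out_aligned, quiet = TRUE)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$effect_allele, h1$effect_allele)
})

test_that("row-local filters commute and global sign flips leave estimates unchanged", {
  set.seed(31)
  s <- make_stats(
    n = 30,
    effect_allele = sample(c("A", "C"), 30, TRUE),
    other_allele = sample(c("G", "T"), 30, TRUE),
    eaf = runif(30, 0.001, 0.999),
    beta = rnorm(30, 0, 0.1), se = runif(30, 0.005, 0.05)
  )
  a <- compute_f_statistics(filter_maf_and_palindromes(s), quiet = TRUE)
  b_stats <- compute_f_statistics(s, f_threshold = 10, quiet = TRUE)
  keep_ids <- filter_maf_and_palindromes(s)$records$variant_id
  b <- b_stats[b_stats$variant_id %in% keep_ids, ]
  expect_setequal(a$variant_id, b$variant_id)

  sim <- simulate_gwas_pair(simulation_config(n_snps = 10, seed = 5))
  h <- hset_from_sim(sim)
  h_neg <- h
  h_neg$beta_exp <- -h$beta_exp
  h_neg$beta_out <- -h$beta_out
  expect_equal(abs(mr_ivw(h_neg)$beta), abs(mr_ivw(h)$beta))
  expect_equal(abs(mr_egger(h_neg)$beta), abs(mr_egger(h)$beta))
  expect_equal(
    abs(mr_weighted_median(h_neg, n_boot = 50, seed = 1)$beta),
    abs(mr_weighted_median(h, n_boot = 50, seed = 1)$beta)
  )
})
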
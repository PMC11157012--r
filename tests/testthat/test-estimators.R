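test_that("wald ratio follows the first-order formulas", {
  h <- make_hset(0.1, 0.01, 0.05, 0.01)
  e <- mr_wald_ratio(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1)
  # null numerator: beta 0, p 1
  e0 <- mr_wald_ratio(make_hset(0.1, 0.01, 0, 0.01))
  expect_equal(e0$beta, 0)
  expect_equal(e0$pval, 1)
  # sign handling
  en <- mr_wald_ratio(make_hset(-0.2, 0.01, 0.04, 0.02))
  expect_equal(en$beta, -0.2)
  expect_equal(en$se, 0.1)
  expect_error(mr_wald_ratio(make_hset(0, 0.01, 0.1, 0.01)),
               class = "mr_undefined_ratio")
})

test_that("IVW reduces to the Wald ratio at J = 1 and is exact on homogeneous sets", {
  h1 <- make_hset(0.12, 0.015, 0.05, 0.02)
  expect_equal(mr_ivw(h1)$beta, mr_wald_ratio(h1)$beta)
  expect_equal(mr_ivw(h1)$se, mr_wald_ratio(h1)$se)
  # two rows with identical ratios: beta equals the ratio, Q = 0,
  # random-effects SE equals fixed
  h2 <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.03, 0.06),
                  c(0.01, 0.02))
  e <- mr_ivw(h2)
  expect_equal(e$beta, 0.3)
  expect_equal(e$q_stat, 0)
  expect_equal(e$se, e$se_fixed)
  expect_error(mr_ivw(h2[0, ]), class = "mr_empty_set")
})

test_that("IVW equals an independent weighted-least-squares solve through the origin", {
  set.seed(42)
  for (i in 1:100) {
    h <- make_hset(rnorm(5, 0.1, 0.05) + 0.05, runif(5, 0.005, 0.02),
                   rnorm(5, 0.02, 0.02), runif(5, 0.005, 0.05))
    e <- mr_ivw(h, model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    expect_equal(e$beta, unname(coef(fit)), tolerance = 1e-9)
    # fixed-effect SE equals the unit-residual-variance WLS SE
    se_wls <- unname(sqrt(diag(vcov(fit))) / summary(fit)$sigma)
    expect_equal(e$se_fixed, se_wls, tolerance = 1e-9)
  }
})

test_that("IVW point estimate is invariant to rescaling all weights", {
  sim <- simulate_gwas_pair(simulation_config(n_snps = 8, seed = 9))
  h <- hset_from_sim(sim)
  h_scaled <- h
  h_scaled$se_out <- h$se_out * 3  # w -> w / 9 uniformly
  expect_equal(mr_ivw(h_scaled)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
})

test_that("MR-Egger recovers a planted intercept and slope", {
  set.seed(7)
  J <- 40
  be <- runif(J, 0.05, 0.2)
  so <- runif(J, 0.002, 0.005)
  bo <- 0.02 + 0.4 * be + rnorm(J, 0, 1e-5)
  h <- make_hset(be, rep(0.001, J), bo, so)
  e <- mr_egger(h)
  expect_equal(e$beta, 0.4, tolerance = 1e-2)
  expect_equal(e$intercept, 0.02, tolerance = 1e-3)
  # p-values use t(J - 2)
  expect_equal(e$pval,
               2 * pt(-abs(e$beta / e$se), J - 2), tolerance = 1e-12)
})

test_that("MR-Egger rejects degenerate designs and too-few instruments", {
  h_const <- make_hset(rep(0.1, 4), 0.01, c(0.02, 0.03, 0.04, 0.05), 0.01)
  expect_error(mr_egger(h_const), class = "mr_singular_design")
  expect_error(mr_egger(make_hset(c(0.1, 0.2), 0.01, c(0.02, 0.03), 0.01)),
               class = "mr_insufficient_instruments")
})

test_that("MR-Egger is invariant to per-SNP sign flips", {
  sim <- simulate_gwas_pair(simulation_config(n_snps = 10, seed = 13))
  h <- hset_from_sim(sim)
  h_flip <- h
  h_flip$beta_exp[3] <- -h$beta_exp[3]
  h_flip$beta_out[3] <- -h$beta_out[3]
  e1 <- mr_egger(h)
  e2 <- mr_egger(h_flip)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-12)
  expect_equal(e2$intercept, e1$intercept, tolerance = 1e-12)
})

test_that("the weighted median interpolates the 50% weighted percentile", {
  # 3 rows, equal weights: the middle ratio
  h <- make_hset(rep(0.1, 3), 0.01, c(0.01, 0.03, 0.09), rep(0.01, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.3)
  # unequal weights vs the brute-force percentile oracle
  set.seed(17)
  for (i in 1:50) {
    J <- sample(3:9, 1)
    be <- runif(J, 0.05, 0.3)
    so <- runif(J, 0.005, 0.05)
    bo <- rnorm(J, 0.05, 0.05)
    h <- make_hset(be, 0.01, bo, so)
    wm <- mr_weighted_median(h, n_boot = 10, seed = i)
    expect_equal(wm$beta, brute_weighted_median(bo / be, be^2 / so^2),
                 tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(h[1:2, ], seed = 1),
               class = "mr_insufficient_instruments")
})

test_that("the weighted-median bootstrap is seed-deterministic and leaves global RNG alone", {
  sim <- simulate_gwas_pair(simulation_config(n_snps = 12, seed = 3))
  h <- hset_from_sim(sim)
  set.seed(999)
  before <- .Random.seed
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(before, .Random.seed)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c_$se))
})

test_that("odds-ratio transforms match the closed form and published rounding", {
  expect_equal(round(to_odds_ratio(0, 0.1)[["or"]], 3), 1)
  # ln(1.232) = 0.209 at 3 dp: the published log-OR convention
  expect_equal(round(to_odds_ratio(0.209, 0.05)[["or"]], 3), 1.232)
  o <- to_odds_ratio(0.5, 0.1)
  expect_equal(unname(o), c(exp(0.5), exp(0.5 - 0.196), exp(0.5 + 0.196)),
               tolerance = 1e-12)
  e <- mr_ivw(make_hset(c(0.1, 0.11, 0.2), 0.01, c(0.02, 0.01, 0.05), 0.01))
  expect_equal(e$or, exp(e$beta))
  expect_true(e$ci_low < e$or && e$or < e$ci_high)
  # reported p consistent with beta/se under the normal reference
  expect_equal(e$pval, 2 * pnorm(-abs(e$beta / e$se)), tolerance = 1e-9)
})

test_that("IVW confidence intervals attain near-nominal coverage on valid instruments", {
  covered <- logical(1000)
  for (i in 1:1000) {
    sim <- simulate_gwas_pair(scenario_presets("valid", seed = 300000 + i,
                                               n_snps = 30))
    e <- mr_ivw(hset_from_sim(sim))
    lo <- e$beta - 1.96 * e$se
    hi <- e$beta + 1.96 * e$se
    covered[i] <- lo <= 0.2 && 0.2 <= hi
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
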
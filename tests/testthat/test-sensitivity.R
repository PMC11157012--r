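test_that("Cochran's Q matches hand arithmetic and its degenerate cases", {
  # identical ratios: Q = 0, p = 1
  h0 <- make_hset(c(0.1, 0.2), 0.01, c(0.03, 0.06), c(0.01, 0.02))
  q0 <- cochran_q(h0)
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_pval, 1)
  # two rows, hand-computed: r = (0.5, 0.2), w = (100, 400)
  h <- make_hset(c(0.1, 0.2), 0.01, c(0.05, 0.04), c(0.01, 0.01))
  q <- cochran_q(h)
  b <- (100 * 0.5 + 400 * 0.2) / 500
  expect_equal(q$q_stat, 100 * (0.5 - b)^2 + 400 * (0.2 - b)^2,
               tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(q$q_stat, 1, lower.tail = FALSE))
  expect_error(cochran_q(h[1, ]), class = "mr_insufficient_instruments")
})

test_that("Q is relabeling-invariant and only shrinks when a SNP is removed", {
  set.seed(5)
  for (i in 1:20) {
    J <- sample(4:10, 1)
    h <- make_hset(runif(J, 0.05, 0.3), 0.01, rnorm(J, 0.02, 0.03),
                   runif(J, 0.005, 0.05))
    q_full <- cochran_q(h)$q_stat
    perm <- sample(J)
    expect_equal(cochran_q(h[perm, ])$q_stat, q_full, tolerance = 1e-9)
    j <- sample(J, 1)
    expect_lte(cochran_q(h[-j, ])$q_stat, q_full + 1e-12)
  }
})

test_that("the Egger intercept test re-exports the regression intercept and needs J >= 3", {
  sim <- simulate_gwas_pair(simulation_config(n_snps = 10, seed = 2))
  h <- hset_from_sim(sim)
  t_int <- egger_intercept_test(h)
  e <- mr_egger(h)
  expect_equal(t_int$intercept, e$intercept)
  expect_equal(t_int$intercept_pval, e$intercept_pval)
  expect_error(egger_intercept_test(h[1:2, ]),
               class = "mr_insufficient_instruments")
})

test_that("the Egger intercept test is calibrated and powered", {
  reject_null <- reject_pleio <- logical(500)
  for (i in 1:500) {
    clean <- simulate_gwas_pair(scenario_presets("valid", seed = 40000 + i))
    reject_null[i] <- egger_intercept_test(
      hset_from_sim(clean))$intercept_pval < 0.05
    pleio <- simulate_gwas_pair(
      scenario_presets("directional_pleio", seed = 41000 + i)
    )
    reject_pleio[i] <- egger_intercept_test(
      hset_from_sim(pleio))$intercept_pval < 0.05
  }
  expect_gte(mean(reject_null), 0.02)
  expect_lte(mean(reject_null), 0.08)
  expect_gt(mean(reject_pleio), 0.5)
})

test_that("leave-one-out reduces to the other SNP's Wald ratio at J = 2", {
  h <- make_hset(c(0.1, 0.2), 0.01, c(0.05, 0.04), c(0.01, 0.01))
  loo <- leave_one_out(h)
  expect_equal(loo$beta[1], mr_wald_ratio(h[2, ])$beta)
  expect_equal(loo$beta[2], mr_wald_ratio(h[1, ])$beta)
  expect_error(leave_one_out(h[1, ]),
               class = "mr_insufficient_instruments")
})

test_that("leave-one-out is stable on homogeneous sets and ranks a planted outlier first", {
  set.seed(8)
  be <- runif(5, 0.1, 0.3)
  h <- make_hset(be, 0.001, 0.3 * be + rnorm(5, 0, 1e-4), 0.003)
  loo <- leave_one_out(h)
  full <- attr(loo, "full")
  expect_true(all(abs(loo$beta - full$beta) < full$se_fixed))
  # one grossly displaced SNP: excluding exactly it moves the estimate most
  h_out <- h
  h_out$beta_out[4] <- h_out$beta_out[4] + 0.05
  loo2 <- leave_one_out(h_out)
  full2 <- attr(loo2, "full")
  expect_equal(which.max(abs(loo2$beta - full2$beta)), 4L)
})

test_that("MR-PRESSO is seed-deterministic and spares clean data", {
  sim <- simulate_gwas_pair(scenario_presets("valid", seed = 19))
  h <- hset_from_sim(sim)
  a <- mr_presso(h, n_sim = 300, seed = 4)
  b <- mr_presso(h, n_sim = 300, seed = 4)
  expect_identical(a, b)
  expect_gt(a$global_pval, 0.05)
  expect_length(a$outlier_ids, 0)
  expect_null(a$corrected_ivw)
  expect_error(mr_presso(h[1:3, ], seed = 1),
               class = "mr_insufficient_instruments")
})

test_that("MR-PRESSO flags a planted 10x outlier and the corrected IVW improves", {
  sim <- simulate_gwas_pair(
    scenario_presets("with_outliers", seed = 101, n_outliers = 1)
  )
  h <- hset_from_sim(sim)
  p <- mr_presso(h, n_sim = 1000, seed = 55)
  planted <- sim$truth$variant_id[sim$truth$outlier]
  expect_true(planted %in% p$outlier_ids)
  expect_lte(p$global_pval, 0.05)
  raw <- mr_ivw(h)
  expect_lt(abs(p$corrected_ivw$beta - 0.2), abs(raw$beta - 0.2))
  expect_true(!is.null(p$distortion_pval))
})

test_that("adjudication follows the J-dispatch and heterogeneity rules", {
  # J = 1: wald only, nothing assessable
  w <- mr_wald_ratio(make_hset(0.1, 0.01, 0.05, 0.01))
  rep1 <- adjudicate_robustness(w)
  expect_equal(rep1$adjudication, "wald_only")
  expect_equal(rep1$pleiotropy_status, "not_assessable")
  # J = 2: IVW primary, pleiotropy not assessable
  h2 <- make_hset(c(0.1, 0.2), 0.01, c(0.05, 0.04), 0.01)
  rep2 <- adjudicate_robustness(mr_ivw(h2), q = cochran_q(h2))
  expect_equal(rep2$adjudication, "ivw_primary")
  expect_equal(rep2$pleiotropy_status, "not_assessable")
  # heterogeneous set: weighted median becomes primary
  sim <- simulate_gwas_pair(scenario_presets("balanced_pleio", seed = 23))
  h <- hset_from_sim(sim)
  q <- cochran_q(h)
  expect_lt(q$q_pval, 0.05)
  wm <- mr_weighted_median(h, n_boot = 100, seed = 1)
  rep3 <- adjudicate_robustness(mr_ivw(h), wm_est = wm, q = q,
                                egger = egger_intercept_test(h))
  expect_equal(rep3$adjudication, "wm_primary")
  expect_true(rep3$heterogeneity_flag)
  expect_identical(rep3$primary, wm)
  # homogeneous set: IVW stays primary
  simv <- simulate_gwas_pair(scenario_presets("valid", seed = 29))
  hv <- hset_from_sim(simv)
  qv <- cochran_q(hv)
  expect_gt(qv$q_pval, 0.05)
  rep4 <- adjudicate_robustness(
    mr_ivw(hv), wm_est = mr_weighted_median(hv, n_boot = 100, seed = 2),
    q = qv, egger = egger_intercept_test(hv)
  )
  expect_equal(rep4$adjudication, "ivw_primary")
})
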
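# helpers building summary-level multivariable designs directly

mv_design <- function(X, se_X, y, se_y, ids = NULL) {
  K <- ncol(X)
  ids <- ids %||% paste0("X", seq_len(K))
  df <- data.frame(variant_id = sprintf("rs%04d", seq_len(nrow(X))))
  for (k in seq_len(K)) {
    df[[paste0("beta_", ids[k])]] <- X[, k]
    df[[paste0("se_", ids[k])]] <- se_X[, k]
  }
  df$beta_out <- y
  df$se_out <- se_y
  structure(df, exposure_ids = ids, outcome_id = "Y",
            n_snp_per_exposure = stats::setNames(rep(nrow(X), K), ids),
            class = c("mvmr_set", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the instrument union carries each SNP once with both exposures' effects", {
  # two exposures with disjoint significant sets plus one shared SNP
  e1 <- make_stats(n = 5, variant_id = paste0("rs", 1:5),
                   pval = c(1e-10, 1e-9, 0.5, 0.5, 0.5), beta = 0.1,
                   se = 0.01, trait_id = "E1")
  e2 <- make_stats(n = 5, variant_id = paste0("rs", 1:5),
                   pval = c(0.5, 1e-12, 0.5, 1e-9, 0.5), beta = 0.12,
                   se = 0.01, trait_id = "E2")
  out <- make_stats(n = 5, variant_id = paste0("rs", 1:5),
                    beta = 0.02, se = 0.01, trait_id = "Y")
  d <- build_mvmr_design(list(e1, e2), out, ld = NULL, quiet = TRUE)
  # rs1, rs2 (once), rs4 significant in at least one exposure
  expect_setequal(d$variant_id, c("rs1", "rs2", "rs4"))
  expect_equal(sum(d$variant_id == "rs2"), 1L)
  expect_true(all(c("beta_E1", "se_E1", "beta_E2", "se_E2") %in% names(d)))
  counts <- attr(d, "n_snp_per_exposure")
  expect_equal(unname(counts["E1"]), 2L)  # rs1, rs2
  expect_equal(unname(counts["E2"]), 2L)  # rs2, rs4
})

test_that("the union row count equals brute-force set algebra on a 3-exposure design", {
  set.seed(12)
  ids <- sprintf("rs%03d", 1:40)
  stats3 <- lapply(1:3, function(k) {
    p <- runif(40)
    p[sample(40, 8)] <- 1e-10
    make_stats(n = 40, variant_id = ids, pval = p, beta = 0.1, se = 0.01,
               trait_id = paste0("E", k))
  })
  out <- make_stats(n = 40, variant_id = ids, beta = 0.02, se = 0.01,
                    trait_id = "Y")
  d <- build_mvmr_design(stats3, out, ld = NULL, quiet = TRUE)
  union_ids <- unique(unlist(lapply(stats3, function(s) {
    s$records$variant_id[s$records$pval < 5e-8]
  })))
  expect_setequal(d$variant_id, union_ids)
})

test_that("under-identified and collinear designs raise classed errors", {
  e1 <- make_stats(n = 2, variant_id = c("rs1", "rs2"), pval = 1e-10,
                   trait_id = "E1")
  e2 <- make_stats(n = 2, variant_id = c("rs1", "rs2"), pval = 1e-10,
                   trait_id = "E2")
  out <- make_stats(n = 2, variant_id = c("rs1", "rs2"), trait_id = "Y")
  expect_error(build_mvmr_design(list(e1, e2), out, ld = NULL, quiet = TRUE),
               class = "mr_underidentified")
  X <- cbind(c(0.1, 0.2, 0.3, 0.4), 2 * c(0.1, 0.2, 0.3, 0.4))
  d <- mv_design(X, matrix(0.01, 4, 2), rnorm(4, 0.02, 0.01), rep(0.01, 4),
                 ids = c("A", "B"))
  expect_error(mvmr_ivw(d), class = "mr_collinearity")
})

test_that("K = 1 multivariable IVW equals univariable IVW on identical rows", {
  set.seed(3)
  be <- runif(6, 0.05, 0.2)
  bo <- rnorm(6, 0.03, 0.02)
  so <- runif(6, 0.005, 0.02)
  d <- mv_design(cbind(be), cbind(rep(0.01, 6)), bo, so, ids = "E")
  mv <- mvmr_ivw(d)$E
  uv <- mr_ivw(make_hset(be, 0.01, bo, so))
  expect_equal(mv$beta, uv$beta, tolerance = 1e-12)
  expect_equal(mv$se, uv$se, tolerance = 1e-12)
})

test_that("orthogonal exposures recover their univariable effects; estimates permute with columns", {
  set.seed(14)
  J <- 60
  # block-orthogonal: each exposure instrumented by its own SNPs
  g1 <- c(runif(J / 2, 0.1, 0.3), rep(0, J / 2))
  g2 <- c(rep(0, J / 2), runif(J / 2, 0.1, 0.3))
  y <- 0.3 * g1 - 0.2 * g2 + rnorm(J, 0, 0.002)
  X <- cbind(g1, g2)
  d <- mv_design(X, matrix(0.005, J, 2), y, rep(0.002, J),
                 ids = c("A", "B"))
  fits <- mvmr_ivw(d)
  expect_equal(fits$A$beta, 0.3, tolerance = 0.01)
  expect_equal(fits$B$beta, -0.2, tolerance = 0.01)
  d_perm <- mv_design(X[, 2:1], matrix(0.005, J, 2), y, rep(0.002, J),
                      ids = c("B", "A"))
  fits_perm <- mvmr_ivw(d_perm)
  expect_equal(fits_perm$A$beta, fits$A$beta, tolerance = 1e-10)
  expect_equal(fits_perm$B$beta, fits$B$beta, tolerance = 1e-10)
})

test_that("a fully mediated total effect vanishes as a direct effect", {
  set.seed(15)
  J <- 80
  # E1 acts on Y only through E2: per-SNP E2 effect = a * E1 effect for
  # E1's instruments, plus E2's own instruments
  g1 <- c(runif(J / 2, 0.1, 0.3), rep(0, J / 2))
  g2_own <- c(rep(0, J / 2), runif(J / 2, 0.1, 0.3))
  a <- 0.8; b <- 0.5
  g2 <- a * g1 + g2_own
  y <- b * g2 + rnorm(J, 0, 0.002)
  # univariable estimate over E1's instruments is the total effect a*b
  h_uni <- make_hset(g1[1:(J / 2)], 0.005, y[1:(J / 2)], 0.002)
  expect_equal(mr_ivw(h_uni)$beta, a * b, tolerance = 0.02)
  d <- mv_design(cbind(g1, g2), matrix(0.005, J, 2), y, rep(0.002, J),
                 ids = c("E1", "E2"))
  fits <- mvmr_ivw(d)
  expect_equal(fits$E1$beta, 0, tolerance = 0.02)
  expect_equal(fits$E2$beta, b, tolerance = 0.02)
})

test_that("multivariable IVW recovers planted direct effects (0.2, 0.5, 0, 0.1)", {
  truth <- c(0.2, 0.5, 0, 0.1)
  K <- 4; J <- 60; R <- 500
  est <- matrix(NA_real_, R, K)
  set.seed(160)
  for (r in 1:R) {
    X_true <- matrix(runif(J * K, -0.2, 0.2), J, K)
    se_x <- matrix(0.002, J, K)
    X_obs <- X_true + rnorm(J * K, 0, 0.002)
    se_y <- rep(0.01, J)
    y <- drop(X_true %*% truth) + rnorm(J, 0, 0.01)
    d <- mv_design(X_obs, se_x, y, se_y)
    est[r, ] <- vapply(mvmr_ivw(d), function(e) e$beta, numeric(1))
  }
  mc_se <- apply(est, 2, sd) / sqrt(R)
  bias <- colMeans(est) - truth
  expect_true(all(abs(bias) <= 3 * mc_se))
})
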
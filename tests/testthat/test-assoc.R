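fixture_assoc <- function(n = 400, seed = 1, r2 = 0.05) {
  set.seed(seed)
  cov <- as.matrix(simulate_covariates(n, seed = seed))
  score <- rnorm(n)
  y <- simulate_phenotype(score, cov, pheno_model(r2), seed = seed + 1)
  list(y = y, score = score, cov = cov)
}

test_that("a constant score yields a zero increment instead of an error", {
  f <- fixture_assoc()
  r <- incremental_r2(f$y, rep(3, length(f$y)), f$cov)
  expect_equal(r$incremental_r2, 0)
  expect_equal(r$coefficient_p, 1)
})

test_that("incremental R2 equals the residual-on-residual partial-correlation oracle", {
  for (s in 1:3) {
    f <- fixture_assoc(seed = s)
    r <- incremental_r2(f$y, f$score, f$cov)
    expect_equal(r$incremental_r2, delta_r2_oracle(f$y, f$score, f$cov),
                 tolerance = 1e-10)
    # and the p-value matches the textbook lm t-test
    fit <- stats::lm(f$y ~ f$cov + f$score)
    expect_equal(r$coefficient_p,
                 summary(fit)$coefficients["f$score", 4], tolerance = 1e-9)
  }
})

test_that("incremental R2 is invariant to affine rescaling of score and covariates", {
  f <- fixture_assoc(seed = 4)
  r0 <- incremental_r2(f$y, f$score, f$cov)
  r1 <- incremental_r2(f$y, 100 * f$score - 7, sweep(f$cov, 2, c(2, 10, rep(0.5, 10)), "*"))
  expect_equal(r0$incremental_r2, r1$incremental_r2, tolerance = 1e-10)
  expect_equal(r0$coefficient_p, r1$coefficient_p, tolerance = 1e-10)
})

test_that("a pure-noise predictor has the expected small positive R2 bias", {
  n <- 200
  f <- fixture_assoc(n = n, seed = 5, r2 = 0)
  set.seed(99)
  est <- vapply(1:300, function(i)
    incremental_r2(f$y, rnorm(n), f$cov)$incremental_r2, numeric(1))
  k <- ncol(f$cov) + 1
  expect_equal(mean(est), 1 / (n - k), tolerance = 0.35)
})

test_that("the threshold scan reports all rows and flags the best threshold", {
  ds <- simulate_genotypes(sim_gen_config(300, 500, maf_range = c(0.1, 0.5),
                                          seed = 6))
  ss <- simulate_summary_stats(ds$variants, seed = 7)
  h <- harmonize_alleles(info_filter(ss$scz), ds)
  m <- score_individuals(ds, h)
  cov <- as.matrix(simulate_covariates(300, seed = 8))
  y <- simulate_phenotype(m$scores[, 5], cov, pheno_model(0.1), seed = 9)
  scan <- threshold_scan(y, m, cov)
  expect_equal(nrow(scan), 8)
  expect_equal(sum(scan$best), 1)
  expect_equal(scan$incremental_r2[scan$best],
               max(scan$incremental_r2))

  single <- m
  single$scores <- m$scores[, 5, drop = FALSE]
  single$thresholds <- m$thresholds[5]
  single$n_snps <- m$n_snps[5]
  s1 <- threshold_scan(y, single, cov)
  expect_true(s1$best[1])
})

test_that("signal concentrated at small p makes the smallest thresholds win", {
  ds <- simulate_genotypes(sim_gen_config(500, 300, maf_range = c(0.2, 0.5),
                                          seed = 10))
  st <- data.frame(SNP = ds$variants$id, CHR = 1L, BP = ds$variants$pos,
                   effect = 0, flip = FALSE,
                   P = seq(0.0001, 0.9999, length.out = 300))
  causal <- st$P < 0.001
  st$effect[causal] <- 0.3
  st$effect[!causal] <- local({set.seed(11); rnorm(sum(!causal), 0, 0.3)})
  true_score <- naive_scores(ds, st[causal, ], threshold = 1)
  y <- simulate_phenotype(true_score, NULL, pheno_model(0.4), seed = 12)
  m <- score_individuals(ds, st)
  scan <- threshold_scan(y, m, NULL)
  expect_equal(scan$threshold[which(scan$best)], 0.001)
})

test_that("permuted phenotypes show only noise-level increments", {
  ds <- simulate_genotypes(sim_gen_config(300, 200, maf_range = c(0.1, 0.5),
                                          seed = 13))
  ss <- simulate_summary_stats(ds$variants, seed = 14)
  m <- score_individuals(ds, harmonize_alleles(ss$scz, ds))
  cov <- as.matrix(simulate_covariates(300, seed = 15))
  y <- simulate_phenotype(m$scores[, 8], cov, pheno_model(0.2), seed = 16)
  y_perm <- local({set.seed(17); sample(y)})
  scan <- threshold_scan(y_perm, m, cov)
  expect_true(all(scan$incremental_r2 < 0.05))
})

test_that("quintile changes are zero-referenced and correct on hand-built data", {
  expect_equal(quintile_summary(rnorm(50), rep(2, 50))$change, rep(0, 5))

  pgs <- 1:50
  q <- quintile_summary(pgs, pgs * 2)
  expect_true(all(diff(q$change) > 0))
  expect_equal(q$change[1], 0)

  pgs10 <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  y10 <- c(50, 10, 90, 30, 70, 20, 80, 40, 100, 60)
  q10 <- quintile_summary(pgs10, y10)
  expect_equal(q10$n, rep(2L, 5))
  expect_equal(q10$mean_phenotype, c(15, 35, 55, 75, 95))
  expect_equal(q10$change, c(0, 20, 40, 60, 80))
  expect_error(quintile_summary(1:4, 1:4), "too few")
})

test_that("a single-variant region reduces to the covariate-adjusted F-test", {
  ds <- simulate_genotypes(sim_gen_config(200, 1, maf_range = c(0.3, 0.5),
                                          seed = 18))
  cov <- as.matrix(simulate_covariates(200, seed = 19))
  y <- local({set.seed(20); rnorm(200)}) + 0.2 * ds$dosages[, 1]
  gt <- gene_based_test(ds, y, cov)
  expect_equal(gt$n_pcs, 1)
  full <- stats::lm(y ~ cov + ds$dosages[, 1])
  base <- stats::lm(y ~ cov)
  expect_equal(gt$p_value, stats::anova(base, full)[2, "Pr(>F)"],
               tolerance = 1e-9)
})

test_that("the gene-based test detects a real single-SNP effect in a region", {
  ds <- simulate_region_genotypes(sim_gen_config(400, 20,
                                                 maf_range = c(0.2, 0.5),
                                                 seed = 21))
  cov <- as.matrix(simulate_covariates(400, seed = 22))
  hits <- vapply(1:20, function(r) {
    y <- local({set.seed(300 + r); rnorm(400)}) + 0.5 * ds$dosages[, 7]
    gene_based_test(ds, y, cov)$p_value
  }, numeric(1))
  expect_gt(mean(hits < 0.05), 0.9)
})

test_that("gene-based null p-values are roughly uniform", {
  ds <- simulate_region_genotypes(sim_gen_config(250, 15,
                                                 maf_range = c(0.1, 0.5),
                                                 seed = 23))
  cov <- as.matrix(simulate_covariates(250, seed = 24))
  set.seed(25)
  pv <- vapply(1:300, function(r)
    gene_based_test(ds, rnorm(250), cov)$p_value, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
})
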
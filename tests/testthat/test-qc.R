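clean_cohort <- function(n = 120, m = 400, seed = 1, ...) {
  simulate_genotypes(sim_gen_config(n, m, maf_range = c(0.25, 0.5),
                                    seed = seed, ...))
}

test_that("sample QC removes high-missingness and aberrant-heterozygosity individuals", {
  g <- clean_cohort()
  # individual 1: 3% of calls missing
  miss_idx <- seq_len(ceiling(0.03 * ncol(g$dosages)))
  g$dosages[1, miss_idx] <- NA
  # individual 2: heterozygous everywhere (het deviation >> 0.2)
  g$dosages[2, ] <- 1L
  res <- sample_qc(g)
  rem <- res$report$removed_individuals
  expect_equal(rem$reason[rem$id == "IND00001"], "missingness")
  expect_equal(rem$reason[rem$id == "IND00002"], "heterozygosity")
  # a clean individual is retained
  expect_true("IND00003" %in% res$dataset$individuals$id)
})

test_that("variant QC applies the MAF, HWE and missingness filters", {
  g <- clean_cohort(n = 200)
  # variant 1: rare (MAF ~ 0.005)
  g$dosages[, 1] <- 0L
  g$dosages[1:2, 1] <- 1L
  # variant 2: gross HWE violation (all heterozygous)
  g$dosages[, 2] <- 1L
  # variant 3: 5/200 missing
  g$dosages[1:5, 3] <- NA
  res <- variant_qc(g)
  rem <- res$report$removed_variants
  expect_equal(rem$reason[rem$id == "rs000001"], "maf")
  expect_equal(rem$reason[rem$id == "rs000002"], "hwe")
  expect_equal(rem$reason[rem$id == "rs000003"], "missingness")
  expect_true("rs000004" %in% res$dataset$variants$id)
})

test_that("the high-quality set enforces its stricter criteria", {
  g <- clean_cohort(n = 150)
  hq0 <- high_quality_set(g)
  expect_gt(length(hq0), 0)
  # push variant 1 to MAF ~ 0.15: excluded
  g$dosages[, 1] <- stats::rbinom(150, 2, 0.15)
  # variant 2: one missing call: excluded
  g$dosages[1, 2] <- NA
  hq <- high_quality_set(g)
  expect_false("rs000001" %in% hq)
  expect_false("rs000002" %in% hq)
})

test_that("LD pruning keeps one of a duplicated pair and spares independent variants", {
  g <- clean_cohort(n = 500, m = 30, seed = 9)
  g$dosages[, 2] <- g$dosages[, 1]       # perfect LD
  kept <- ld_prune(g, g$variants$id)
  expect_equal(sum(c("rs000001", "rs000002") %in% kept), 1)
  expect_true(all(g$variants$id[-(1:2)] %in% kept))
})

test_that("pruned survivor sets satisfy the pairwise r2 constraint exhaustively", {
  g <- simulate_genotypes(sim_gen_config(800, 40, maf_range = c(0.25, 0.5),
                                         ld_block_size = 10, ld_rho = 0.9,
                                         seed = 10))
  kept <- ld_prune(g, g$variants$id, r2_thresh = 0.1)
  expect_lt(max_pairwise_r2(g, kept), 0.1)
  expect_lt(length(kept), 40)
})

test_that("relatedness filtering removes one member per related pair", {
  g <- clean_cohort(n = 80, m = 1500, seed = 11)
  dup <- g$dosages[1, ]
  g$dosages[2, ] <- dup                  # duplicated individual
  res <- relatedness_filter(g, g$variants$id, seed = 4)
  rem <- res$report$removed_individuals
  expect_true(any(rem$id %in% c("IND00001", "IND00002")))
  expect_false(all(c("IND00001", "IND00002") %in% res$dataset$individuals$id))
  # unrelated cohort: nothing removed
  g2 <- clean_cohort(n = 60, m = 1500, seed = 12)
  res2 <- relatedness_filter(g2, g2$variants$id, seed = 4)
  expect_equal(nrow(res2$report$removed_individuals), 0)
})

test_that("PCA screening removes a constructed ancestry outlier and recomputes PCs", {
  g <- clean_cohort(n = 100, m = 600, seed = 13)
  # contaminant: dosages pushed towards the alternate allele at 30% of variants
  shift <- seq_len(0.3 * ncol(g$dosages))
  g$dosages[1, shift] <- 2L
  res <- pca_outlier_filter(g, g$variants$id)
  expect_true("IND00001" %in% res$report$removed_individuals$id)
  pcs <- res$report$pc_matrix
  expect_equal(nrow(pcs), 99)
  # PC columns orthogonal
  cross <- crossprod(pcs)
  expect_lt(max(abs(cross[upper.tri(cross)])) / max(diag(cross)), 1e-8)
  # homogeneous cohort: no outliers
  g2 <- clean_cohort(n = 100, m = 600, seed = 14)
  res2 <- pca_outlier_filter(g2, g2$variants$id)
  expect_equal(nrow(res2$report$removed_individuals), 0)
})

test_that("the QC cascade is consistent and idempotent on clean output", {
  g <- simulate_genotypes(sim_gen_config(120, 1500, maf_range = c(0.1, 0.5),
                                         ld_block_size = 5, ld_rho = 0.4,
                                         n_related_pairs = 1,
                                         missing_rate = 0.003, seed = 15))
  res <- qc_cascade(g, seed = 2)
  rep <- res$report
  expect_equal(nrow(g$dosages) - nrow(rep$removed_individuals),
               nrow(res$dataset$dosages))
  expect_equal(ncol(g$dosages) - nrow(rep$removed_variants),
               ncol(res$dataset$dosages))
  expect_equal(anyDuplicated(rep$removed_individuals$id), 0)
  expect_equal(anyDuplicated(rep$removed_variants$id), 0)

  res2 <- qc_cascade(res$dataset, seed = 2)
  expect_equal(nrow(res2$report$removed_individuals), 0)
  expect_equal(nrow(res2$report$removed_variants), 0)
})
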
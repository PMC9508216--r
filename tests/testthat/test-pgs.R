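small_dataset <- function(n = 100, m = 50, seed = 1) {
  simulate_genotypes(sim_gen_config(n, m, maf_range = c(0.1, 0.5),
                                    seed = seed))
}

stats_for <- function(dataset, seed = 2, ...) {
  simulate_summary_stats(dataset$variants, seed = seed, ...)
}

test_that("allele harmonization keeps, flips and drops the right variants", {
  ds <- genotype_dataset(
    matrix(c(0L, 1L, 2L, 2L, 1L, 0L, 1L, 1L, 0L), 3, 3,
           dimnames = list(NULL, c("v1", "v2", "v3"))),
    data.frame(id = c("a", "b", "c"), sex = 1),
    data.frame(id = c("v1", "v2", "v3"), chrom = 1L, pos = c(100L, 200L, 300L),
               allele1 = c("A", "G", "A"), allele2 = c("G", "A", "T")))
  st <- data.frame(SNP = c("v1", "v2", "v3", "v4"), CHR = 1, BP = c(100, 200, 300, 400),
                   A1 = c("A", "A", "A", "C"), A2 = c("G", "G", "T", "T"),
                   BETA = c(0.5, -0.25, 1, 1), P = rep(0.01, 4))
  h <- harmonize_alleles(st, ds)
  expect_setequal(h$SNP, c("v1", "v2"))     # v3 palindromic, v4 unmatched
  expect_false(h$flip[h$SNP == "v1"])
  expect_true(h$flip[h$SNP == "v2"])        # dataset stores G/A
  cnt <- attr(h, "counts")
  expect_equal(unname(cnt["palindromic"]), 1)
  expect_equal(unname(cnt["unmatched"]), 1)
})

test_that("scores are invariant to the stored allele orientation", {
  ds <- small_dataset()
  ss <- stats_for(ds)
  h <- harmonize_alleles(ss$scz, ds)
  ref <- score_individuals(ds, h)

  flipped <- ds
  flipped$variants$allele1 <- ds$variants$allele2
  flipped$variants$allele2 <- ds$variants$allele1
  flipped$dosages <- 2L - ds$dosages
  h2 <- harmonize_alleles(ss$scz, flipped)
  flip_scores <- score_individuals(flipped, h2)
  expect_identical(ref$scores, flip_scores$scores)
  expect_identical(ref$n_snps, flip_scores$n_snps)
})

test_that("info filtering uses a strict less-than rule", {
  st <- data.frame(SNP = c("a", "b", "c"), INFO = c(0.95, 0.89, 0.9))
  kept <- info_filter(st)
  expect_setequal(kept$SNP, c("a", "c"))    # exactly 0.9 passes
  expect_error(info_filter(st[, "SNP", drop = FALSE]), "info column")
})

test_that("concordance splitting follows effect signs and flags bad orientation", {
  scz <- data.frame(SNP = c("a", "b", "c"), A1 = "A", A2 = "G",
                    effect = log(c(1.2, 0.8, 1.1)))
  iq <- data.frame(SNP = c("a", "b", "c"), A1 = "A", A2 = "G",
                   effect = c(0.3, 0.1, 0))
  sp <- split_by_concordance(scz, iq)
  expect_equal(sp$concordant, "a")   # OR > 1 with beta > 0
  expect_equal(sp$discordant, "b")   # OR < 1 with beta > 0
  expect_equal(sp$zero, "c")

  # opposite stored orientation in the IQ table is re-aligned, not misread
  iq2 <- data.frame(SNP = c("a", "b", "c"), A1 = "G", A2 = "A",
                    effect = -c(0.3, 0.1, 0))
  expect_identical(split_by_concordance(scz, iq2), sp)

  iq3 <- iq
  iq3$A1 <- c("A", "C", "A")
  expect_error(split_by_concordance(scz, iq3), "orientation mismatch")
})

test_that("the concordant/discordant split partitions non-null shared variants", {
  ds <- small_dataset(n = 200, m = 2000, seed = 3)
  ss <- stats_for(ds, concordant_fraction = 0.7, seed = 4)
  scz_h <- harmonize_alleles(ss$scz, ds)
  iq_h <- harmonize_alleles(ss$iq, ds)
  sp <- split_by_concordance(scz_h, iq_h)
  shared <- intersect(scz_h$SNP, iq_h$SNP)
  expect_length(intersect(sp$concordant, sp$discordant), 0)
  expect_setequal(c(sp$concordant, sp$discordant, sp$zero), shared)
  # realized fraction near 0.7 among non-null variants
  frac <- length(sp$concordant) / (length(sp$concordant) + length(sp$discordant))
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.21 / length(shared)) + 0.02)
})

test_that("clumping keeps the most significant member of an LD group", {
  ds <- small_dataset(n = 400, m = 10, seed = 5)
  ds$dosages[, 2] <- ds$dosages[, 1]       # duplicate pair 10 kb apart
  st <- data.frame(SNP = ds$variants$id, CHR = 1L, BP = ds$variants$pos,
                   effect = 0.1, P = c(1e-8, 1e-4, runif(8, 0.1, 0.9)))
  kept <- clump_variants(st, ds)
  expect_true("rs000001" %in% kept)
  expect_false("rs000002" %in% kept)
  expect_true(all(st$SNP[-(1:2)] %in% kept))

  # no clumping among independent variants
  ds2 <- small_dataset(n = 400, m = 10, seed = 6)
  st2 <- st
  kept2 <- clump_variants(st2, ds2)
  expect_length(kept2, 10)
})

test_that("clump survivors are pairwise below the r2 threshold (exhaustive check)", {
  ds <- simulate_genotypes(sim_gen_config(500, 30, maf_range = c(0.2, 0.5),
                                          ld_block_size = 10, ld_rho = 0.9,
                                          seed = 7))
  st <- data.frame(SNP = ds$variants$id, CHR = 1L, BP = ds$variants$pos,
                   effect = 0.1, P = runif(30))
  kept <- clump_variants(st, ds, r2_thresh = 0.1, window_kb = 1000)
  expect_lt(max_pairwise_r2(ds, kept), 0.1)
})

test_that("scoring reproduces a hand dot-product and the strict threshold rule", {
  ds <- genotype_dataset(
    matrix(c(0L, 1L, 2L, 1L), 2, 2, dimnames = list(NULL, c("v1", "v2"))),
    data.frame(id = c("a", "b"), sex = 1),
    data.frame(id = c("v1", "v2"), chrom = 1L, pos = c(1L, 2L),
               allele1 = "A", allele2 = "G"))
  st <- data.frame(SNP = c("v1", "v2"), effect = c(0.5, -0.25),
                   flip = FALSE, P = c(1e-4, 0.01))
  m <- score_individuals(ds, st, grid = c(0.001, 1))
  expect_equal(unname(m$scores[, "PT_1"]), c(-0.5, 0.25))
  # p = 0.01 contributes at t = 1 but not at t = 0.001
  expect_equal(m$n_snps, c(1L, 2L))
  expect_equal(unname(m$scores[, "PT_0.001"]), c(0, 0.5))

  st0 <- transform(st, effect = 0)
  expect_true(all(score_individuals(ds, st0)$scores == 0))
})

test_that("SNP inclusion is monotone in the threshold and differences are the added SNPs", {
  ds <- small_dataset(n = 50, m = 300, seed = 8)
  ss <- stats_for(ds, seed = 9)
  h <- harmonize_alleles(info_filter(ss$scz), ds)
  m <- score_individuals(ds, h)
  expect_true(all(diff(m$n_snps) >= 0))
  # score at t' minus score at t equals the contribution of SNPs with p in [t, t')
  grid <- m$thresholds
  for (k in seq_len(length(grid) - 1)) {
    mid <- h[h$P >= grid[k] & h$P < grid[k + 1], ]
    addition <- if (nrow(mid)) naive_scores(ds, mid, threshold = 2) else 0
    expect_equal(unname(m$scores[, k + 1] - m$scores[, k]), unname(addition),
                 tolerance = 1e-10)
  }
})

test_that("vectorized scores equal the naive per-individual loop", {
  ds <- simulate_genotypes(sim_gen_config(60, 400, maf_range = c(0.05, 0.5),
                                          missing_rate = 0.01, seed = 10))
  ss <- stats_for(ds, seed = 11)
  h <- harmonize_alleles(ss$scz, ds)
  m <- score_individuals(ds, h, grid = c(0.1, 1))
  expect_equal(unname(m$scores[, 1]), naive_scores(ds, h, 0.1),
               tolerance = 1e-10)
  expect_equal(unname(m$scores[, 2]), naive_scores(ds, h, 1),
               tolerance = 1e-10)
})

test_that("gene-region restriction respects bounds, flanks and chromosome", {
  st <- data.frame(SNP = c("a", "b", "c", "d"),
                   CHR = c(22, 22, 22, 21),
                   BP = c(39946758, 39900000, 40125000, 40000000))
  r <- restrict_to_region(st, 22, 39946758, 40105740, flank_kb = 20)
  expect_setequal(r$SNP, c("a", "c"))   # c inside the +20 kb flank
  expect_error(restrict_to_region(st, 22, 50, 10), "inverted")
})
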
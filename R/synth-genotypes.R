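#' Configuration for the genotype simulator
#'
#' @param n_individuals number of individuals.
#' @param n_variants number of biallelic variants.
#' @param maf_range length-2 vector of minor-allele-frequency bounds in
#'   (0, 0.5]; per-variant MAFs are drawn uniformly in this range.
#' @param ld_block_size number of consecutive variants per correlated block.
#' @param ld_rho latent (haplotype-level) correlation within a block;
#'   0 gives independent variants.
#' @param n_related_pairs number of cryptically related pairs to create by
#'   haplotype copying (expected pi-hat about 0.5 per pair, i.e.
#'   parent-offspring-like sharing).
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return validated list of class `sim_gen_config`.
#' @export
sim_gen_config <- function(n_individuals, n_variants,
                           maf_range = c(0.05, 0.5),
                           ld_block_size = 1, ld_rho = 0,
                           n_related_pairs = 0, missing_rate = 0,
                           seed = 1L) {
  if (n_variants < ld_block_size)
    stop("n_variants must be >= ld_block_size")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho, n_related_pairs = as.integer(n_related_pairs),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_gen_config")
}

#' Simulate a biallelic genotype dataset
#'
#' Dosages in `{0, 1, 2}` (count of allele1) are generated as the sum of two
#' latent haplotypes. Each haplotype is thresholded from a block-diagonal
#' Gaussian copula: within a block of `ld_block_size` variants the latent
#' normals have exchangeable correlation `ld_rho`, which induces linkage
#' disequilibrium while keeping exact Hardy-Weinberg marginals at each
#' variant's MAF. Related pairs are created by copying one haplotype of the
#' first pair member into the second, so the expected genome-wide pi-hat of
#' the pair is about 0.5.
#'
#' Variants are laid out on chromosome 1 at 5-kb spacing (chromosome 22 with
#' gene-region coordinates is available via [simulate_region_genotypes()]).
#'
#' @param config a [sim_gen_config()].
#' @return object of class `genotype_dataset`: list with `dosages`
#'   (individuals x variants matrix, NA = missing), `individuals`
#'   (data frame: `id`, `sex`), `variants` (data frame: `id`, `chrom`,
#'   `pos`, `allele1`, `allele2`, `maf`), and `related_pairs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_gen_config"))
  n <- config$n_individuals
  m <- config$n_variants
  with_seed(config$seed, {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    h1 <- simulate_haplotypes(n, maf, config$ld_block_size, config$ld_rho)
    h2 <- simulate_haplotypes(n, maf, config$ld_block_size, config$ld_rho)

    related_pairs <- NULL
    if (config$n_related_pairs > 0) {
      if (2 * config$n_related_pairs > n)
        stop("too many related pairs for cohort size")
      ids <- matrix(seq_len(2 * config$n_related_pairs), ncol = 2, byrow = TRUE)
      for (k in seq_len(nrow(ids))) {
        # second member inherits haplotype 1 of the first member
        h1[ids[k, 2], ] <- h1[ids[k, 1], ]
      }
      related_pairs <- data.frame(id1 = sprintf("IND%05d", ids[, 1]),
                                  id2 = sprintf("IND%05d", ids[, 2]))
    }

    dos <- h1 + h2
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      dos[miss] <- NA_integer_
    }

    alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), m, 2)
    same <- alleles[, 1] == alleles[, 2]
    while (any(same)) {   # ensure biallelic pairs differ
      alleles[same, 2] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
      same <- alleles[, 1] == alleles[, 2]
    }

    individuals <- data.frame(id = sprintf("IND%05d", seq_len(n)),
                              sex = sample(1:2, n, replace = TRUE))
    variants <- data.frame(id = sprintf("rs%06d", seq_len(m)),
                           chrom = 1L, pos = 5000L * seq_len(m),
                           allele1 = alleles[, 1], allele2 = alleles[, 2],
                           maf = maf)
    rownames(dos) <- individuals$id
    colnames(dos) <- variants$id
    genotype_dataset(dos, individuals, variants, related_pairs)
  })
}

#' @rdname simulate_genotypes
#' @param dosages individuals x variants matrix with entries in
#'   `{0, 1, 2, NA}`.
#' @param individuals data frame with columns `id`, `sex`.
#' @param variants data frame with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`.
#' @param related_pairs optional data frame of simulated related pairs.
#' @export
genotype_dataset <- function(dosages, individuals, variants,
                             related_pairs = NULL) {
  if (nrow(dosages) != nrow(individuals) || ncol(dosages) != nrow(variants))
    stop("dosage matrix dimensions do not match metadata")
  if (anyDuplicated(variants$id)) stop("variant IDs must be unique")
  structure(list(dosages = dosages, individuals = individuals,
                 variants = variants, related_pairs = related_pairs),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Simulate genotypes confined to a genomic region
#'
#' Same generative model as [simulate_genotypes()] but with variant
#' positions drawn uniformly inside `[start_bp, end_bp]` on `chrom`, for
#' exercising gene-region scoring and gene-based tests.
#'
#' @inheritParams simulate_genotypes
#' @param chrom chromosome code.
#' @param start_bp,end_bp region bounds (1-based, inclusive).
#' @return a `genotype_dataset`.
#' @export
simulate_region_genotypes <- function(config, chrom = 22L,
                                      start_bp = 39946758, end_bp = 40105740) {
  ds <- simulate_genotypes(config)
  m <- nrow(ds$variants)
  pos <- with_seed(child_seed(config$seed, 97L),
                   sort(sample(seq(start_bp, end_bp), m)))
  ds$variants$chrom <- as.integer(chrom)
  ds$variants$pos <- as.integer(pos)
  ds
}

# one haplotype matrix (n x m of 0/1) from a block-exchangeable Gaussian copula
simulate_haplotypes <- function(n, maf, block_size, rho) {
  m <- length(maf)
  if (rho == 0 || block_size == 1) {
    z <- matrix(stats::rnorm(n * m), n, m)
  } else {
    z <- matrix(0, n, m)
    starts <- seq(1L, m, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, m)
      k <- e - s + 1L
      shared <- stats::rnorm(n)
      z[, s:e] <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
    }
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = n)) * 1L
}
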
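#' Genotype quality-control cascade
#'
#' Implements the standard array-QC sequence used before polygenic scoring:
#' sample filters (missingness, heterozygosity), variant filters (MAF, HWE,
#' missingness), construction of a stricter high-quality SNP set, LD
#' pruning, relatedness exclusion and principal-component outlier removal.
#' Filters run in that fixed order; every removal records exactly one
#' first-triggering reason.
#'
#' @name qc
NULL

empty_report <- function() {
  list(removed_individuals = data.frame(id = character(0),
                                        reason = character(0)),
       removed_variants = data.frame(id = character(0),
                                     reason = character(0)),
       pruned_snp_set = character(0), pc_matrix = NULL, log = character(0))
}

merge_report <- function(a, b) {
  a$removed_individuals <- rbind(a$removed_individuals, b$removed_individuals)
  a$removed_variants <- rbind(a$removed_variants, b$removed_variants)
  if (length(b$pruned_snp_set)) a$pruned_snp_set <- b$pruned_snp_set
  if (!is.null(b$pc_matrix)) a$pc_matrix <- b$pc_matrix
  a$log <- c(a$log, b$log)
  a
}

drop_individuals <- function(dataset, ids) {
  if (!length(ids)) return(dataset)
  keep <- !(dataset$individuals$id %in% ids)
  dataset$dosages <- dataset$dosages[keep, , drop = FALSE]
  dataset$individuals <- dataset$individuals[keep, , drop = FALSE]
  dataset
}

drop_variants <- function(dataset, ids) {
  if (!length(ids)) return(dataset)
  keep <- !(dataset$variants$id %in% ids)
  dataset$dosages <- dataset$dosages[, keep, drop = FALSE]
  dataset$variants <- dataset$variants[keep, , drop = FALSE]
  dataset
}

# per-variant allele1 frequency from non-missing calls
allele_freq <- function(dosages) colMeans(dosages, na.rm = TRUE) / 2

# minor allele frequency
maf_of <- function(dosages) pmin(allele_freq(dosages), 1 - allele_freq(dosages))

#' Sample-level QC
#'
#' Removes individuals with call missingness above `miss_thresh` or with
#' absolute normalized heterozygosity deviation above `het_thresh`. The
#' heterozygosity statistic is `(observed het - expected het) / expected
#' het` per individual, with the expectation `2 p q` summed over the
#' variants used; it is computed on the high-quality SNP set when one can
#' be formed (falling back to all variants otherwise). Sex-mismatch
#' checking is a logged no-op: sex chromosomes are outside this pipeline.
#'
#' @param dataset a `genotype_dataset`.
#' @param miss_thresh maximum per-individual missing call rate.
#' @param het_thresh maximum |normalized heterozygosity deviation|.
#' @return list `dataset` (filtered) and `report` delta.
#' @export
sample_qc <- function(dataset, miss_thresh = 0.02, het_thresh = 0.2) {
  if (nrow(dataset$dosages) == 0) stop("empty dataset")
  rep <- empty_report()
  dos <- dataset$dosages

  miss <- rowMeans(is.na(dos))
  bad_miss <- dataset$individuals$id[miss > miss_thresh]

  hq <- tryCatch(high_quality_set(dataset), error = function(e) character(0))
  use <- if (length(hq) >= 50) dos[, hq, drop = FALSE] else dos
  p <- allele_freq(use)
  exp_het_var <- 2 * p * (1 - p)
  obs_het <- rowSums(use == 1, na.rm = TRUE)
  exp_het <- as.numeric((!is.na(use)) %*% exp_het_var)
  het_dev <- (obs_het - exp_het) / exp_het
  bad_het <- dataset$individuals$id[abs(het_dev) > het_thresh]
  bad_het <- setdiff(bad_het, bad_miss)   # first-triggering reason only

  rep$removed_individuals <- rbind(
    data.frame(id = bad_miss,
               reason = rep("missingness", length(bad_miss))),
    data.frame(id = bad_het,
               reason = rep("heterozygosity", length(bad_het))))
  rep$log <- c(rep$log, "sex-mismatch check: not evaluated (no sex chromosomes)")
  list(dataset = drop_individuals(dataset, rep$removed_individuals$id),
       report = rep)
}

#' Variant-level QC
#'
#' Removes variants with minor allele frequency below `maf_thresh`, HWE
#' exact p-value below `hwe_thresh`, or missing call rate above
#' `miss_thresh`. MAF is computed on non-missing calls. Reasons are
#' recorded in that order of precedence.
#'
#' @inheritParams sample_qc
#' @param maf_thresh minimum minor allele frequency.
#' @param hwe_thresh minimum HWE exact p-value.
#' @param miss_thresh maximum per-variant missing rate.
#' @export
variant_qc <- function(dataset, maf_thresh = 0.01, hwe_thresh = 1e-6,
                       miss_thresh = 0.02) {
  rep <- empty_report()
  dos <- dataset$dosages
  maf <- maf_of(dos)
  miss <- colMeans(is.na(dos))
  hwe_p <- hwe_pvalues(dos)

  reason <- rep(NA_character_, ncol(dos))
  reason[maf < maf_thresh] <- "maf"
  reason[is.na(reason) & hwe_p < hwe_thresh] <- "hwe"
  reason[is.na(reason) & miss > miss_thresh] <- "missingness"
  bad <- which(!is.na(reason))
  rep$removed_variants <- data.frame(id = dataset$variants$id[bad],
                                     reason = reason[bad])
  list(dataset = drop_variants(dataset, rep$removed_variants$id),
       report = rep)
}

#' High-quality SNP set
#'
#' Stricter criteria (HWE p > 0.02, MAF > 0.20, zero missingness) selecting
#' the variants used for LD pruning, relatedness estimation and PCA only —
#' scoring still uses the full post-QC set.
#'
#' @inheritParams sample_qc
#' @return character vector of variant IDs.
#' @export
high_quality_set <- function(dataset) {
  dos <- dataset$dosages
  maf <- maf_of(dos)
  miss <- colMeans(is.na(dos))
  ok_pre <- maf > 0.20 & miss == 0
  ids <- dataset$variants$id[ok_pre]
  if (!length(ids)) return(character(0))
  hwe_p <- hwe_pvalues(dos[, ids, drop = FALSE])
  ids[hwe_p > 0.02]
}

#' Greedy sliding-window LD pruning
#'
#' Within each `window_size`-variant window (position-sorted within
#' chromosome), variant pairs with genotype squared correlation at or above
#' `r2_thresh` are resolved by dropping the member with the lower MAF (tie:
#' later position), until all retained within-window pairs satisfy
#' `r2 < r2_thresh`; the window then slides by `step`.
#'
#' @inheritParams sample_qc
#' @param snp_set variant IDs to prune (typically [high_quality_set()]).
#' @param r2_thresh r-squared threshold.
#' @param window_size variants per window.
#' @param step window slide in variants.
#' @return character vector of surviving variant IDs.
#' @export
ld_prune <- function(dataset, snp_set, r2_thresh = 0.1, window_size = 200,
                     step = 50) {
  idx <- match(snp_set, dataset$variants$id)
  if (anyNA(idx)) stop("snp_set contains unknown variant IDs")
  v <- dataset$variants[idx, ]
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_along(ord))) {
    if (is.unsorted(order(v$chrom, v$pos))) stop("unsorted input")
    v <- v[ord, ]; idx <- idx[ord]
  }
  dos <- dataset$dosages[, idx, drop = FALSE]
  maf <- maf_of(dos)
  m <- length(idx)
  alive <- rep(TRUE, m)

  for (chr in unique(v$chrom)) {
    in_chr <- which(v$chrom == chr)
    s <- 1L
    repeat {
      win <- in_chr[seq(s, min(s + window_size - 1L, length(in_chr)))]
      cand <- win[alive[win]]
      if (length(cand) > 1) {
        g <- dos[, cand, drop = FALSE]
        r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (any(r2 >= r2_thresh)) {
          hit <- which(r2 >= r2_thresh, arr.ind = TRUE)[1, ]
          pair <- cand[c(hit[1], hit[2])]
          pm <- maf[match(pair, cand)]
          drop_local <- if (pm[1] < pm[2]) hit[1]
                        else if (pm[2] < pm[1]) hit[2]
                        else hit[which.max(v$pos[pair])]
          alive[cand[drop_local]] <- FALSE
          r2[drop_local, ] <- 0
          r2[, drop_local] <- 0
        }
      }
      if (s + window_size - 1L >= length(in_chr)) break
      s <- s + step
    }
  }
  v$id[alive]
}

#' Pairwise relatedness (pi-hat) from a pruned SNP set
#'
#' Method-of-moments estimate of the genome shared identical-by-descent:
#' for individuals i, j, `pi_hat = mean_k (x_ik - 2 p_k)(x_jk - 2 p_k) /
#' (2 p_k (1 - p_k))` over the pruned variants, the standard
#' allele-frequency-standardized genotype covariance, whose expectation is
#' 1 for duplicates/MZ twins, 0.5 for parent-offspring, and 0 for
#' unrelated pairs.
#'
#' @inheritParams ld_prune
#' @return data frame `id1, id2, pi_hat` for all pairs.
#' @export
pi_hat_matrix <- function(dataset, snp_set) {
  idx <- match(snp_set, dataset$variants$id)
  dos <- dataset$dosages[, idx, drop = FALSE]
  p <- allele_freq(dos)
  x <- sweep(dos, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  k <- tcrossprod(x) / length(idx)
  n <- nrow(dos)
  pairs <- which(upper.tri(k), arr.ind = TRUE)
  data.frame(id1 = dataset$individuals$id[pairs[, 1]],
             id2 = dataset$individuals$id[pairs[, 2]],
             pi_hat = k[pairs])
}

#' Relatedness filter
#'
#' For each pair with estimated pi-hat above `pi_hat_thresh`, one member is
#' removed at random (seeded); repeated until no pair exceeds the
#' threshold.
#'
#' @inheritParams ld_prune
#' @param pi_hat_thresh pi-hat threshold.
#' @param seed RNG seed for the random member choice.
#' @export
relatedness_filter <- function(dataset, snp_set, pi_hat_thresh = 0.20,
                               seed = 1L) {
  if (nrow(dataset$dosages) < 2) stop("fewer than 2 individuals")
  rep <- empty_report()
  removed <- character(0)
  with_seed(seed, {
    repeat {
      ph <- pi_hat_matrix(dataset, snp_set)
      hot <- ph[ph$pi_hat > pi_hat_thresh, , drop = FALSE]
      if (nrow(hot) == 0) break
      pair <- hot[order(-hot$pi_hat), ][1, ]
      victim <- if (stats::runif(1) < 0.5) pair$id1 else pair$id2
      removed <- c(removed, victim)
      dataset <- drop_individuals(dataset, victim)
    }
  })
  rep$removed_individuals <- data.frame(
    id = removed, reason = rep("relatedness", length(removed)))
  list(dataset = dataset, report = rep)
}

#' Principal components and PC-outlier exclusion
#'
#' Dosages on the pruned SNP set are standardized per variant (centered at
#' `2 p`, scaled by `sqrt(2 p (1 - p))`) and decomposed by PCA. Individuals
#' deviating more than `sd_thresh` standard deviations on any of the first
#' `n_pcs` components are excluded and the PCs are recomputed once on the
#' remaining individuals; the leading 10 PCs are the association
#' covariates.
#'
#' @inheritParams ld_prune
#' @param n_pcs number of components screened for outliers.
#' @param sd_thresh outlier threshold in per-component SD units.
#' @return list `dataset`, `report` (with `pc_matrix`: individuals x
#'   `n_pcs`, orthogonal columns).
#' @export
pca_outlier_filter <- function(dataset, snp_set, n_pcs = 20, sd_thresh = 6.0) {
  n <- nrow(dataset$dosages)
  n_pcs_eff <- min(n_pcs, n - 1L, length(snp_set))
  if (n_pcs_eff < 1) stop("n_pcs exceeds usable dimensions")
  rep <- empty_report()

  pcs <- dosage_pca(dataset, snp_set, n_pcs_eff)
  z <- scale(pcs)
  out <- which(apply(abs(z), 1, max, na.rm = TRUE) > sd_thresh)
  if (length(out)) {
    rep$removed_individuals <- data.frame(
      id = dataset$individuals$id[out],
      reason = rep("pca_outlier", length(out)))
    dataset <- drop_individuals(dataset, rep$removed_individuals$id)
    n_pcs_eff <- min(n_pcs, nrow(dataset$dosages) - 1L, length(snp_set))
    pcs <- dosage_pca(dataset, snp_set, n_pcs_eff)
  }
  rownames(pcs) <- dataset$individuals$id
  rep$pc_matrix <- pcs
  list(dataset = dataset, report = rep)
}

dosage_pca <- function(dataset, snp_set, n_pcs) {
  idx <- match(snp_set, dataset$variants$id)
  dos <- dataset$dosages[, idx, drop = FALSE]
  p <- allele_freq(dos)
  keep <- p > 0 & p < 1
  dos <- dos[, keep, drop = FALSE]; p <- p[keep]
  x <- sweep(dos, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
}

#' Run the full QC cascade
#'
#' Sample QC, variant QC, high-quality set, LD pruning, relatedness filter,
#' PCA outlier filter — in that order, with one merged report. Re-running
#' the cascade on its own output is a fixed point.
#'
#' @inheritParams sample_qc
#' @param params named list overriding any of the default thresholds
#'   (`miss_thresh`, `het_thresh`, `maf_thresh`, `hwe_thresh`,
#'   `var_miss_thresh`, `r2_thresh`, `window_size`, `prune_step`,
#'   `pi_hat_thresh`, `n_pcs`, `sd_thresh`).
#' @param seed seed for the relatedness tie-break.
#' @return list `dataset` (clean), `report` (QC report with removals, the
#'   pruned SNP set and the PC matrix).
#' @export
qc_cascade <- function(dataset, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    miss_thresh = 0.02, het_thresh = 0.2, maf_thresh = 0.01,
    hwe_thresh = 1e-6, var_miss_thresh = 0.02, r2_thresh = 0.1,
    window_size = 200, prune_step = 50, pi_hat_thresh = 0.20,
    n_pcs = 20, sd_thresh = 6.0), params)
  report <- empty_report()

  s <- sample_qc(dataset, p$miss_thresh, p$het_thresh)
  report <- merge_report(report, s$report)
  v <- variant_qc(s$dataset, p$maf_thresh, p$hwe_thresh, p$var_miss_thresh)
  report <- merge_report(report, v$report)

  hq <- high_quality_set(v$dataset)
  pruned <- ld_prune(v$dataset, hq, p$r2_thresh, p$window_size, p$prune_step)
  report$pruned_snp_set <- pruned
  report$log <- c(report$log,
                  sprintf("high-quality set: %d variants; pruned: %d",
                          length(hq), length(pruned)))

  r <- relatedness_filter(v$dataset, pruned, p$pi_hat_thresh, seed)
  report <- merge_report(report, r$report)
  pc <- pca_outlier_filter(r$dataset, pruned, p$n_pcs, p$sd_thresh)
  report <- merge_report(report, pc$report)

  list(dataset = pc$dataset, report = report)
}
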
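# Independent oracles used across the suite. Each re-derives the quantity
# by a different route than the implementation under test.

# HWE exact p-value by direct enumeration: conditional probability of each
# heterozygote count from the closed-form log-factorial expression.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n - n_A
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  het_vals <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, het_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# naive per-individual polygenic score loop (counts effect-allele copies)
naive_scores <- function(dataset, stats, threshold) {
  idx <- match(stats$SNP, dataset$variants$id)
  n <- nrow(dataset$dosages)
  freq <- colMeans(dataset$dosages, na.rm = TRUE) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (r in seq_len(nrow(stats))) {
      if (stats$P[r] >= threshold) next
      d <- dataset$dosages[i, idx[r]]
      if (is.na(d)) d <- 2 * freq[idx[r]]
      if (!is.null(stats$flip) && stats$flip[r]) d <- 2 - d
      s <- s + d * stats$effect[r]
    }
    out[i] <- s
  }
  out
}

# swap the stored allele orientation of every variant in a dataset
within_flip <- function(g) {
  a1 <- g$variants$allele1
  g$variants$allele1 <- g$variants$allele2
  g$variants$allele2 <- a1
  g$dosages <- 2L - g$dosages
  g
}

# per-individual scoring loop at full scale: one individual at a time,
# plain elementwise arithmetic over that individual's dosage row
naive_oracle_fast <- function(dataset, stats, threshold) {
  idx <- match(stats$SNP, dataset$variants$id)
  freq <- colMeans(dataset$dosages, na.rm = TRUE) / 2
  use <- stats$P < threshold
  eff <- stats$effect[use]
  flip <- if (is.null(stats$flip)) rep(FALSE, sum(use)) else stats$flip[use]
  cols <- idx[use]
  out <- numeric(nrow(dataset$dosages))
  for (i in seq_len(nrow(dataset$dosages))) {
    d <- dataset$dosages[i, cols]
    miss <- is.na(d)
    d[miss] <- 2 * freq[cols][miss]
    d[flip] <- 2 - d[flip]
    out[i] <- sum(d * eff)
  }
  out
}

# residual-on-residual oracle for the R2 increment: the squared partial
# correlation of y and s given C, scaled by the unexplained share of the
# base model (delta R2 = (1 - R2_base) * partial_r^2 algebraically)
delta_r2_oracle <- function(y, s, C) {
  fit_base <- stats::lm(y ~ C)
  ry <- stats::resid(fit_base)
  rs <- stats::resid(stats::lm(s ~ C))
  base_r2 <- summary(fit_base)$r.squared
  (1 - base_r2) * stats::cor(ry, rs)^2
}

# sample-by-sample threshold scan over an RMS step series: returns runs of
# consecutive supra-threshold windows as (first_window, n_windows)
naive_rms_scan <- function(rms, thr) {
  runs <- list()
  i <- 1L
  while (i <= length(rms)) {
    if (rms[i] > thr) {
      j <- i
      while (j < length(rms) && rms[j + 1L] > thr) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i, len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, runs)
}

# exhaustive all-pairs r2 check for pruning/clumping survivor sets
max_pairwise_r2 <- function(dataset, ids) {
  g <- dataset$dosages[, match(ids, dataset$variants$id), drop = FALSE]
  if (ncol(g) < 2) return(0)
  r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  max(r2, na.rm = TRUE)
}
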
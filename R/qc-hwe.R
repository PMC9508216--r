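#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for deviation from Hardy-Weinberg proportions at a
#' biallelic variant. Conditional on the observed allele counts, the
#' probability of every possible heterozygote count is computed by the
#' standard recurrence, and the p-value is the sum of probabilities of
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts (non-negative integers).
#' @param midp if TRUE, return the mid-p value (half weight on the observed
#'   configuration). The ordinary exact p-value is discrete and
#'   conservative; the mid-p variant is the standard choice when checking
#'   the calibration of the test against a uniform reference. QC filtering
#'   uses the default (conservative) p-value.
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration, p = 1
#' hwe_exact_test(50, 0, 50)    # complete heterozygote deficit, p ~ 0
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all-zero genotype counts")
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)   # monomorphic: single possible configuration

  # heterozygote counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_vals))
  # start from the mid-range heterozygote count and recurse both ways:
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2) * (h+1))
  start <- which.min(abs(het_vals - rare * (2 * n - rare) / (2 * n)))
  probs[start] <- 1
  if (start < length(het_vals)) {
    for (i in start:(length(het_vals) - 1L)) {
      h <- het_vals[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (start > 1) {
    for (i in start:2) {
      h <- het_vals[i]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, het_vals)]
  if (midp) {
    at_obs <- abs(probs - p_obs) <= 1e-12 * p_obs
    return(sum(probs[probs < p_obs & !at_obs]) + 0.5 * sum(probs[at_obs]))
  }
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Vectorized HWE exact p-values over a dosage matrix
#'
#' @param dosages individuals x variants matrix in `{0, 1, 2, NA}` (dosage
#'   of allele1).
#' @inheritParams hwe_exact_test
#' @return numeric vector of per-variant exact p-values.
#' @export
hwe_pvalues <- function(dosages, midp = FALSE) {
  apply(dosages, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0), midp = midp)
  })
}
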
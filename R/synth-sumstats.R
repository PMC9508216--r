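#' Simulate paired GWAS summary statistics for schizophrenia and IQ
#'
#' Produces two summary-statistic tables over the same variants: a
#' case-control trait reported as odds ratios (schizophrenia) and a
#' quantitative trait reported as betas (intelligence). A configurable
#' fraction of variants is null (exactly zero effect in both traits,
#' excluded from concordance accounting, since effect direction is
#' undefined at zero). For each non-null variant the sign relationship
#' between log(OR) and beta is drawn Bernoulli(`concordant_fraction`):
#' concordant means higher schizophrenia risk goes with higher IQ (or lower
#' with lower), discordant means the directions oppose.
#'
#' P-values are drawn Uniform(0,1) for null variants and Beta(0.2, 1)
#' (right-skewed towards small values) for non-null variants, so the
#' p-value-threshold grid partitions the set non-trivially. Info scores are
#' Uniform(0.85, 1), so the conventional 0.9 info filter removes roughly a
#' third of rows.
#'
#' @param variants data frame of variant metadata (`id`, `chrom`, `pos`,
#'   `allele1`, `allele2`), typically from a `genotype_dataset`.
#' @param concordant_fraction probability in \[0, 1\] that a non-null
#'   variant has concordant effect directions in the two traits.
#' @param effect_sd SD of non-null log-odds-ratios and |betas|.
#' @param null_fraction fraction of variants with exactly zero effect.
#' @param seed integer seed.
#' @return list with elements `scz` and `iq`, each a `summary_stats` data
#'   frame with columns `SNP, CHR, BP, A1, A2, OR` (or `BETA`), `SE, P,
#'   INFO`, plus a logical `truth` data frame (`null`, `concordant`).
#' @export
simulate_summary_stats <- function(variants, concordant_fraction = 0.5,
                                   effect_sd = 0.05, null_fraction = 0.2,
                                   seed = 1L) {
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop("concordant_fraction must be in [0, 1]")
  m <- nrow(variants)
  with_seed(seed, {
    is_null <- stats::runif(m) < null_fraction
    log_or <- ifelse(is_null, 0, stats::rnorm(m, 0, effect_sd))
    concord <- stats::runif(m) < concordant_fraction
    beta_mag <- abs(stats::rnorm(m, 0, effect_sd))
    beta <- ifelse(is_null, 0,
                   ifelse(concord, sign(log_or), -sign(log_or)) * beta_mag)

    p_scz <- ifelse(is_null, stats::runif(m), stats::rbeta(m, 0.2, 1))
    p_iq <- ifelse(is_null, stats::runif(m), stats::rbeta(m, 0.2, 1))
    info_scz <- stats::runif(m, 0.85, 1)
    info_iq <- stats::runif(m, 0.85, 1)
    se <- abs(stats::rnorm(m, 0.02, 0.005)) + 1e-4

    base <- data.frame(SNP = variants$id, CHR = variants$chrom,
                       BP = variants$pos, A1 = variants$allele1,
                       A2 = variants$allele2)
    scz <- cbind(base, data.frame(OR = exp(log_or), SE = se, P = p_scz,
                                  INFO = info_scz))
    iq <- cbind(base, data.frame(BETA = beta, SE = se, P = p_iq,
                                 INFO = info_iq))
    class(scz) <- c("summary_stats", "data.frame")
    class(iq) <- c("summary_stats", "data.frame")
    list(scz = scz, iq = iq,
         truth = data.frame(SNP = variants$id, null = is_null,
                            concordant = ifelse(is_null, NA, concord)))
  })
}
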
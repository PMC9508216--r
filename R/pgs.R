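#' Default p-value threshold grid
#'
#' The conventional scoring grid: 0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1.
#' A score at threshold t sums all variants with GWAS p strictly below t
#' (t = 1 therefore includes every variant, since p-values are in (0, 1]).
#'
#' @return numeric vector of 8 thresholds.
#' @export
default_pt_grid <- function() c(0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1)

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize summary statistics to a genotype dataset
#'
#' Matches variants by ID against the dataset and resolves allele
#' orientation. The effect stays expressed per copy of the summary-stats
#' effect allele (converted to the additive scale: `log(OR)` for
#' case-control tables); a `flip` flag records whether the dataset stores
#' the other allele as allele1, so scoring counts effect-allele copies as
#' `2 - dosage` there. This makes polygenic scores invariant to how either
#' side stored the allele pair. Strand-ambiguous palindromic variants
#' (A/T, C/G) are removed; variants absent from either side or with
#' incompatible allele pairs are dropped, with counts recorded.
#'
#' @param stats a `summary_stats` data frame (columns `SNP, CHR, BP, A1,
#'   A2`, `OR` or `BETA`, `P`, optional `INFO`).
#' @param dataset a `genotype_dataset`.
#' @return data frame with columns `SNP, CHR, BP, A1, A2` (stats
#'   orientation), `effect`, `flip`, `P`, `INFO` (if present), plus
#'   attribute `counts` (matched, flipped, palindromic, unmatched,
#'   incompatible).
#' @export
harmonize_alleles <- function(stats, dataset) {
  eff <- effect_column(stats)
  shared <- intersect(stats$SNP, dataset$variants$id)
  if (length(shared) == 0) stop("zero overlapping variants")
  keep <- match(shared, stats$SNP)
  st <- stats[keep, ]
  eff <- eff[keep]
  dv <- dataset$variants[match(shared, dataset$variants$id), ]

  pal <- paste(st$A1, st$A2, sep = "/") %in% PALINDROMIC
  direct <- st$A1 == dv$allele1 & st$A2 == dv$allele2
  swapped <- st$A1 == dv$allele2 & st$A2 == dv$allele1
  ok <- !pal & (direct | swapped)

  out <- data.frame(SNP = shared[ok], CHR = dv$chrom[ok], BP = dv$pos[ok],
                    A1 = st$A1[ok], A2 = st$A2[ok],
                    effect = eff[ok], flip = swapped[ok], P = st$P[ok])
  if ("INFO" %in% names(st)) out$INFO <- st$INFO[ok]
  attr(out, "counts") <- c(
    matched = sum(direct & !pal), flipped = sum(swapped & !pal),
    palindromic = sum(pal), unmatched = length(stats$SNP) - length(shared),
    incompatible = sum(!pal & !direct & !swapped))
  out
}

effect_column <- function(stats) {
  if ("BETA" %in% names(stats)) return(stats$BETA)
  if ("OR" %in% names(stats)) {
    if (any(stats$OR <= 0)) stop("odds ratios must be positive")
    return(log(stats$OR))
  }
  stop("summary statistics need an OR or BETA column")
}

#' Filter summary statistics on imputation info score
#'
#' Removes rows with info score strictly below `threshold` (a row at
#' exactly the threshold passes).
#'
#' @param stats summary statistics with an `INFO` column.
#' @param threshold minimum info score.
#' @export
info_filter <- function(stats, threshold = 0.9) {
  if (!"INFO" %in% names(stats)) stop("missing info column")
  stats[stats$INFO >= threshold, , drop = FALSE]
}

#' Split variants by schizophrenia-IQ effect-direction concordance
#'
#' Variants present in both tables are partitioned by the sign relationship
#' of their effects: concordant when higher schizophrenia risk (log OR > 0)
#' goes with higher IQ (beta > 0), or lower risk with lower IQ; discordant
#' when the directions oppose. Variants with a zero effect in either trait
#' belong to neither subset. Before comparing signs the IQ effect is
#' re-oriented to the schizophrenia table's effect allele when the two
#' tables stored the pair in opposite orientation; incompatible allele
#' pairs raise an error.
#'
#' @param scz,iq harmonized tables (from [harmonize_alleles()]) with
#'   columns `SNP`, `A1`, `A2`, `effect`.
#' @return list `concordant`, `discordant`, `zero` (character vectors of
#'   variant IDs).
#' @export
split_by_concordance <- function(scz, iq) {
  shared <- intersect(scz$SNP, iq$SNP)
  si <- match(shared, scz$SNP)
  qi <- match(shared, iq$SNP)
  s <- scz$effect[si]
  q <- iq$effect[qi]
  if (all(c("A1", "A2") %in% names(scz)) &&
      all(c("A1", "A2") %in% names(iq))) {
    same <- scz$A1[si] == iq$A1[qi] & scz$A2[si] == iq$A2[qi]
    opp <- scz$A1[si] == iq$A2[qi] & scz$A2[si] == iq$A1[qi]
    if (any(!same & !opp))
      stop("orientation mismatch: incompatible allele pairs for shared variants")
    q <- ifelse(opp, -q, q)
  }
  concordant <- shared[sign(s) == sign(q) & s != 0 & q != 0]
  discordant <- shared[sign(s) == -sign(q) & s != 0 & q != 0]
  zero <- shared[s == 0 | q == 0]
  list(concordant = concordant, discordant = discordant, zero = zero)
}

#' Greedy p-value-aware LD clumping
#'
#' Variants are visited in order of ascending p-value; each index variant
#' removes all not-yet-clumped variants within `window_kb` kilobases on the
#' same chromosome whose genotype r-squared with it is at least
#' `r2_thresh`. The analysis cohort itself is the LD reference.
#'
#' @param stats harmonized stats (`SNP, CHR, BP, P`).
#' @param dataset a `genotype_dataset` providing LD.
#' @param r2_thresh r-squared threshold.
#' @param window_kb clumping window in kb.
#' @return character vector of retained variant IDs.
#' @export
clump_variants <- function(stats, dataset, r2_thresh = 0.1, window_kb = 250) {
  if (any(is.na(stats$BP))) stop("positions missing")
  idx <- match(stats$SNP, dataset$variants$id)
  dos <- dataset$dosages[, idx, drop = FALSE]
  ord <- order(stats$P)
  state <- rep("free", nrow(stats))   # free | index | clumped
  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    near <- which(state == "free" &
                    stats$CHR == stats$CHR[i] &
                    abs(stats$BP - stats$BP[i]) <= window_kb * 1000)
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(dos[, i], dos[, near, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      state[near[r2 >= r2_thresh]] <- "clumped"
    }
  }
  stats$SNP[state == "index"]
}

#' Compute polygenic scores over a threshold grid
#'
#' For each threshold t, `score_i = sum over {j : p_j < t, j in subset} of
#' dosage_ij * effect_j`, with effects on the additive scale (log OR for
#' case-control traits). Missing dosages are mean-imputed as twice the
#' cohort allele frequency, keeping scores comparable across individuals.
#'
#' @param dataset a `genotype_dataset`.
#' @param stats harmonized stats (`SNP, effect, P`), already info-filtered
#'   and optionally clumped.
#' @param grid numeric vector of p-value thresholds (strictly increasing).
#' @param subset optional character vector restricting scoring to these
#'   variant IDs (e.g. a concordance subset or a clump survivors list).
#' @param label subset label stored with the result.
#' @return object of class `pgs_matrix`: list with `scores` (individuals x
#'   thresholds), `n_snps` (per-threshold SNP counts), `thresholds`,
#'   `label`.
#' @export
score_individuals <- function(dataset, stats, grid = default_pt_grid(),
                              subset = NULL, label = "all") {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (!is.null(subset)) stats <- stats[stats$SNP %in% subset, , drop = FALSE]
  idx <- match(stats$SNP, dataset$variants$id)
  if (anyNA(idx)) stop("stats contain variants absent from the dataset")
  dos <- dataset$dosages[, idx, drop = FALSE]
  if (ncol(dos)) {
    p <- allele_freq(dos)
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- 2 * p[j]
    if (!is.null(stats$flip) && any(stats$flip)) {
      # count copies of the stats effect allele
      fl <- which(stats$flip)
      dos[, fl] <- 2 - dos[, fl, drop = FALSE]
    }
  }
  n <- nrow(dataset$dosages)
  scores <- matrix(0, n, length(grid),
                   dimnames = list(dataset$individuals$id,
                                   paste0("PT_", grid)))
  n_snps <- integer(length(grid))
  for (k in seq_along(grid)) {
    use <- which(stats$P < grid[k])
    n_snps[k] <- length(use)
    if (length(use) == 0) {
      warning(sprintf("no SNPs pass threshold %g; scores set to 0", grid[k]))
      next
    }
    scores[, k] <- dos[, use, drop = FALSE] %*% stats$effect[use]
  }
  structure(list(scores = scores, n_snps = n_snps, thresholds = grid,
                 label = label), class = "pgs_matrix")
}

#' @export
print.pgs_matrix <- function(x, ...) {
  cat(sprintf("pgs_matrix [%s]: %d individuals x %d thresholds (SNPs: %s)\n",
              x$label, nrow(x$scores), length(x$thresholds),
              paste(x$n_snps, collapse = ", ")))
  invisible(x)
}

#' Restrict summary statistics to a gene region
#'
#' Keeps variants on `chrom` with position inside
#' `[start_bp - flank_kb*1000, end_bp + flank_kb*1000]`, inclusive. The
#' default flank of 20 kb matches conventional gene-region scoring.
#'
#' @param stats table with `CHR` and `BP` columns.
#' @param chrom chromosome code.
#' @param start_bp,end_bp gene bounds (1-based, inclusive).
#' @param flank_kb flank added on both sides, in kb.
#' @export
restrict_to_region <- function(stats, chrom, start_bp, end_bp, flank_kb = 20) {
  if (start_bp > end_bp) stop("inverted interval")
  lo <- start_bp - flank_kb * 1000
  hi <- end_bp + flank_kb * 1000
  stats[stats$CHR == chrom & stats$BP >= lo & stats$BP <= hi, , drop = FALSE]
}
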
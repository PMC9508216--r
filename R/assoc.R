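#' Incremental R2 of a polygenic score over a covariate base model
#'
#' Fits the base ordinary-least-squares model `phenotype ~ covariates`
#' (sex, age and 10 genetic principal components in the standard analysis)
#' and the full model adding the score, and returns the increase in the
#' (unadjusted) coefficient of determination together with the two-sided
#' t-test p-value of the score coefficient. A score column collinear with
#' the base design (e.g. constant) contributes a well-defined increment of
#' zero rather than an error.
#'
#' @param phenotype numeric response vector.
#' @param pgs_column numeric score vector.
#' @param covariates numeric matrix/data frame of covariates, or NULL.
#' @param threshold optional threshold identity carried into the result.
#' @return object of class `association_result`: list with `threshold`,
#'   `incremental_r2`, `coefficient_p`, `n`, `base_r2`.
#' @export
incremental_r2 <- function(phenotype, pgs_column, covariates = NULL,
                           threshold = NA_real_) {
  n <- length(phenotype)
  if (length(pgs_column) != n) stop("phenotype/pgs length mismatch")
  if (stats::var(phenotype) == 0) stop("constant phenotype")
  x_base <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows do not match phenotype")
    x_base <- cbind(x_base, covariates)
  }
  if (n <= ncol(x_base) + 2) stop("too few observations for the model")
  if (qr(x_base)$rank < ncol(x_base))
    stop("rank-deficient design: collinear covariates")

  fit_base <- stats::lm.fit(x_base, phenotype)
  tss <- sum((phenotype - mean(phenotype))^2)
  base_r2 <- 1 - sum(fit_base$residuals^2) / tss

  x_full <- cbind(x_base, PGS = pgs_column)
  fit_full <- stats::lm.fit(x_full, phenotype)
  if (fit_full$rank < ncol(x_full)) {
    # score collinear with the base design: zero increment, no evidence
    res <- list(threshold = threshold, incremental_r2 = 0,
                coefficient_p = 1, n = n, base_r2 = base_r2)
    return(structure(res, class = "association_result"))
  }
  full_r2 <- 1 - sum(fit_full$residuals^2) / tss

  df <- n - ncol(x_full)
  sigma2 <- sum(fit_full$residuals^2) / df
  xi <- chol2inv(qr.R(fit_full$qr))
  xtx_inv <- matrix(0, ncol(x_full), ncol(x_full))
  xtx_inv[fit_full$qr$pivot, fit_full$qr$pivot] <- xi
  se <- sqrt(sigma2 * xtx_inv[ncol(x_full), ncol(x_full)])
  tval <- fit_full$coefficients["PGS"] / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  structure(list(threshold = threshold, incremental_r2 = full_r2 - base_r2,
                 coefficient_p = as.numeric(pval), n = n, base_r2 = base_r2),
            class = "association_result")
}

#' Scan a polygenic-score threshold grid
#'
#' Runs [incremental_r2()] for every threshold column of a `pgs_matrix`
#' and reports all results, flagging the best threshold (maximal
#' incremental R2, ties broken by smaller coefficient p-value). All rows
#' are always returned — the scan never reports only its winner.
#'
#' @param phenotype numeric response.
#' @param pgs_matrix a [score_individuals()] result.
#' @param covariates covariate matrix/data frame or NULL.
#' @return data frame with one row per threshold (`threshold`,
#'   `incremental_r2`, `coefficient_p`, `n`, `base_r2`, `n_snps`, `best`).
#' @export
threshold_scan <- function(phenotype, pgs_matrix, covariates = NULL) {
  stopifnot(inherits(pgs_matrix, "pgs_matrix"))
  rows <- lapply(seq_along(pgs_matrix$thresholds), function(k) {
    r <- incremental_r2(phenotype, pgs_matrix$scores[, k], covariates,
                        threshold = pgs_matrix$thresholds[k])
    data.frame(threshold = r$threshold, incremental_r2 = r$incremental_r2,
               coefficient_p = r$coefficient_p, n = r$n, base_r2 = r$base_r2,
               n_snps = pgs_matrix$n_snps[k])
  })
  out <- do.call(rbind, rows)
  best <- order(-out$incremental_r2, out$coefficient_p)[1]
  out$best <- seq_len(nrow(out)) == best
  out
}

#' Phenotype change by polygenic-score quintile
#'
#' Ranks individuals into five near-equal groups by score (stable ties,
#' group sizes differing by at most one) and reports each group's mean
#' phenotype minus the lowest-quintile mean, the lowest quintile being the
#' reference at exactly zero.
#'
#' @param pgs_column numeric score vector.
#' @param phenotype numeric response.
#' @return data frame `quintile`, `n`, `mean_phenotype`, `change` plus
#'   attribute `boundaries` (score cut points).
#' @export
quintile_summary <- function(pgs_column, phenotype) {
  n <- length(pgs_column)
  if (n < 5) stop("too few individuals for quintiles")
  ord <- order(pgs_column)               # stable: ties by original order
  q <- integer(n)
  sizes <- diff(round(seq(0, n, length.out = 6)))
  q[ord] <- rep(1:5, times = sizes)
  means <- tapply(phenotype, q, mean)
  out <- data.frame(quintile = 1:5, n = as.integer(table(q)),
                    mean_phenotype = as.numeric(means),
                    change = as.numeric(means - means[1]))
  attr(out, "boundaries") <- tapply(pgs_column, q, max)[1:4]
  out
}

#' Gene-based multi-SNP association test
#'
#' Principal-components regression over a gene region: phenotype and
#' standardized region dosages are residualized on the covariates
#' (including an intercept); the genotype residual matrix is decomposed by
#' PCA and the components jointly explaining at least `var_retain` of its
#' variance are retained; their joint fit to the residualized phenotype is
#' evaluated by an F-test with the covariate degrees of freedom removed
#' from the error term. With a single variant in the region this reduces
#' exactly to the covariate-adjusted single-SNP F-test.
#'
#' @param dataset a `genotype_dataset` already restricted to the region.
#' @param phenotype numeric response.
#' @param covariates covariate matrix/data frame or NULL.
#' @param var_retain cumulative variance fraction retained (default 0.999).
#' @return list `p_value`, `f_stat`, `df1`, `df2`, `n_variants`, `n_pcs`.
#' @export
gene_based_test <- function(dataset, phenotype, covariates = NULL,
                            var_retain = 0.999) {
  g <- dataset$dosages
  if (ncol(g) < 1) stop("region contains no variants")
  n <- length(phenotype)
  if (nrow(g) != n) stop("phenotype does not match dataset individuals")

  p <- allele_freq(g)
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("region contains no polymorphic variants")
  g <- g[, keep, drop = FALSE]; p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0

  x_cov <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  q_cov <- qr(x_cov)
  y_res <- qr.resid(q_cov, phenotype)
  g_res <- qr.resid(q_cov, x)

  sv <- svd(g_res)
  var_expl <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(var_expl >= var_retain)[1]
  pcs <- sv$u[, seq_len(k), drop = FALSE]

  df2 <- n - q_cov$rank - k
  if (df2 < 1) stop("retained PCs exhaust the residual degrees of freedom")
  fit <- stats::lm.fit(pcs, y_res)
  rss0 <- sum(y_res^2)
  rss1 <- sum(fit$residuals^2)
  f <- ((rss0 - rss1) / k) / (rss1 / df2)
  list(p_value = stats::pf(f, k, df2, lower.tail = FALSE), f_stat = f,
       df1 = k, df2 = df2, n_variants = ncol(g), n_pcs = k)
}
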
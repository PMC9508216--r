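#' Phenotype generative model
#'
#' @param target_incremental_r2 population incremental R2 of the true score
#'   over the covariates, in \[0, 1).
#' @param covariate_effects named numeric vector of per-covariate
#'   coefficients (applied column-wise to the covariate matrix).
#' @param noise_sd residual SD in phenotype units.
#' @return list of class `pheno_model`.
#' @export
pheno_model <- function(target_incremental_r2 = 0.052,
                        covariate_effects = NULL, noise_sd = 1) {
  if (target_incremental_r2 < 0 || target_incremental_r2 >= 1)
    stop("target_incremental_r2 must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(target_incremental_r2 = target_incremental_r2,
                 covariate_effects = covariate_effects, noise_sd = noise_sd),
            class = "pheno_model")
}

#' Simulate a phenotype with a known incremental R2
#'
#' Builds `phenotype = covariates %*% effects + gamma * true_score + noise`
#' where `gamma` is solved so the population share of phenotype variance
#' attributable to the score over and above the covariates equals
#' `model$target_incremental_r2`:
#' `gamma^2 = R2 * (V_cov + noise_sd^2) / (V_score_resid * (1 - R2))`,
#' with `V_score_resid` the variance of the score after projecting out the
#' covariates (sample variances are used, so recovery is exact up to the
#' noise draw).
#'
#' @param true_score numeric vector, e.g. a polygenic score column.
#' @param covariates numeric matrix or data frame (one row per individual)
#'   or NULL for a covariate-free model.
#' @param model a [pheno_model()].
#' @param seed integer seed.
#' @return numeric phenotype vector.
#' @export
simulate_phenotype <- function(true_score, covariates = NULL,
                               model = pheno_model(), seed = 1L) {
  n <- length(true_score)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates/true_score dimension mismatch")
    eff <- model$covariate_effects
    if (is.null(eff)) eff <- rep(1, ncol(covariates))
    if (length(eff) != ncol(covariates))
      stop("covariate_effects length must match covariate columns")
    cov_term <- drop(covariates %*% eff)
    score_resid <- stats::lm.fit(cbind(1, covariates), true_score)$residuals
  } else {
    cov_term <- rep(0, n)
    score_resid <- true_score - mean(true_score)
  }

  r2 <- model$target_incremental_r2
  v_resid <- stats::var(score_resid)
  if (r2 > 0 && v_resid <= 0)
    stop("true_score is constant (after covariate adjustment); cannot target a positive R2")
  v_other <- stats::var(cov_term) + model$noise_sd^2
  gamma <- if (r2 == 0) 0
           else if (v_other == 0) 1   # noiseless limit: score passes through
           else sqrt(r2 * v_other / (v_resid * (1 - r2)))
  with_seed(seed,
            cov_term + gamma * true_score + stats::rnorm(n, sd = model$noise_sd))
}

#' Simulate an association-model covariate table
#'
#' Sex (binary), age (years, Uniform 18-60 matching a healthy adult cohort)
#' and `n_pcs` standard-normal stand-ins for genetic principal components.
#'
#' @param n number of individuals.
#' @param n_pcs number of simulated principal-component columns.
#' @param seed integer seed.
#' @return data frame `sex, age, PC1..PCk`.
#' @export
simulate_covariates <- function(n, n_pcs = 10, seed = 1L) {
  with_seed(seed, {
    out <- data.frame(sex = sample(0:1, n, replace = TRUE),
                      age = stats::runif(n, 18, 60))
    pcs <- matrix(stats::rnorm(n * n_pcs), n, n_pcs)
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    cbind(out, pcs)
  })
}
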
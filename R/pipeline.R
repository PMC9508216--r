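#' Default pipeline configuration
#'
#' All analysis parameters default to the conventional values of the
#' spindle-PGS design: 30-s epochs, band-pass +/- 1.5 Hz around the
#' individual peak, 200-ms RMS windows, 1.5-SD threshold, 0.5-3 s
#' durations; QC at MAF 0.01, HWE 1e-6, missingness 0.02, LD pruning r2 <
#' 0.1 in 200-SNP windows, pi-hat 0.20, 6 SD on 20 PCs; info filter 0.9;
#' the 8-threshold PT grid; +/- 20 kb gene flanks. Simulation sizes
#' (cohort 150, 2,000 variants, 10 N2 epochs per subject) are chosen so a
#' full run stays interactive; they are plain config fields.
#'
#' @param seed global seed fanned out to per-stage child seeds.
#' @return nested named list (serializable to YAML).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genotypes = list(n_individuals = 150, n_variants = 2000,
                     maf_range = c(0.05, 0.5), ld_block_size = 10,
                     ld_rho = 0.3, n_related_pairs = 2, missing_rate = 0.005),
    sumstats = list(concordant_fraction = 0.5, effect_sd = 0.05,
                    null_fraction = 0.2),
    spindle = list(mode = "eeg", epochs_per_subject = 10, band = "fast",
                   amplitude_uv = 27.56, noise_pink = 6, noise_white = 1.5,
                   halfwidth_hz = 1.5, rms_window_s = 0.2, threshold_sd = 1.5,
                   min_dur_s = 0.5, max_dur_s = 3.0,
                   density_mean = 2.22, density_sd = 0.38),
    phenotype = list(target_incremental_r2 = 0.052, noise_sd = 1),
    qc = list(miss_thresh = 0.02, het_thresh = 0.2, maf_thresh = 0.01,
              hwe_thresh = 1e-6, var_miss_thresh = 0.02, r2_thresh = 0.1,
              window_size = 200, prune_step = 50, pi_hat_thresh = 0.20,
              n_pcs = 20, sd_thresh = 6.0),
    pgs = list(info_thresh = 0.9, grid = default_pt_grid(), clump = FALSE,
               clump_r2 = 0.1, clump_window_kb = 250),
    assoc = list(n_covariate_pcs = 10),
    gene_region = list(chrom = 1, start_bp = 2e6, end_bp = 3e6,
                       flank_kb = 20)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file path.
#' @param seed fallback seed if the file does not set one.
#' @return config list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(seed), user)
}

validate_config <- function(config) {
  if (config$genotypes$n_individuals < 1)
    stop("invalid config: n_individuals must be >= 1")
  if (config$genotypes$n_variants < 1)
    stop("invalid config: n_variants must be >= 1")
  if (config$phenotype$target_incremental_r2 < 0 ||
      config$phenotype$target_incremental_r2 >= 1)
    stop("invalid config: target_incremental_r2 must be in [0, 1)")
  if (!config$spindle$mode %in% c("eeg", "direct"))
    stop("invalid config: spindle mode must be 'eeg' or 'direct'")
  invisible(TRUE)
}

#' Run the full synthetic spindle-PGS pipeline
#'
#' Executes the analysis chain in order: genotype simulation, paired
#' schizophrenia/IQ summary-statistic simulation, genotype QC (yielding
#' the covariate PCs), polygenic scoring at the threshold grid for the
#' full SNP set and its concordant/discordant strata, phenotype generation
#' as a latent fast-spindle density driven by the true genetic score, EEG
#' simulation and spindle detection per subject (mode `"eeg"`; mode
#' `"direct"` uses the latent density directly), incremental-R2 threshold
#' scans, the quintile summary at the best threshold, and a gene-based
#' test on the configured region. Child seeds are derived from the global
#' seed per stage, so any stage can be reproduced in isolation.
#'
#' @param config from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir optional directory; when given, per-stage outputs
#'   (PLINK files, summary-stat TSVs, spindle summaries, association
#'   tables) and `report.json` are written there.
#' @return the run report (list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  report <- list(seed = seed, timestamp = format(Sys.time(), usetz = TRUE))

  # --- genotypes ------------------------------------------------------
  gcfg <- do.call(sim_gen_config,
                  c(config$genotypes, list(seed = child_seed(seed, 1L))))
  geno <- simulate_genotypes(gcfg)
  report$n_individuals_raw <- nrow(geno$dosages)
  report$n_variants_raw <- ncol(geno$dosages)

  # --- summary statistics --------------------------------------------
  ss <- simulate_summary_stats(
    geno$variants, config$sumstats$concordant_fraction,
    config$sumstats$effect_sd, config$sumstats$null_fraction,
    seed = child_seed(seed, 2L))

  # --- QC -------------------------------------------------------------
  qc <- qc_cascade(geno, config$qc, seed = child_seed(seed, 3L))
  clean <- qc$dataset
  pcs <- qc$report$pc_matrix
  report$n_individuals_clean <- nrow(clean$dosages)
  report$n_variants_clean <- ncol(clean$dosages)
  report$n_removed_individuals <- nrow(qc$report$removed_individuals)
  report$n_removed_variants <- nrow(qc$report$removed_variants)

  # --- polygenic scores ----------------------------------------------
  scz_f <- info_filter(ss$scz, config$pgs$info_thresh)
  iq_f <- info_filter(ss$iq, config$pgs$info_thresh)
  scz_h <- harmonize_alleles(scz_f, clean)
  iq_h <- harmonize_alleles(iq_f, clean)
  split <- split_by_concordance(scz_h, iq_h)
  report$n_concordant <- length(split$concordant)
  report$n_discordant <- length(split$discordant)

  scz_use <- scz_h
  if (isTRUE(config$pgs$clump)) {
    kept <- clump_variants(scz_h, clean, config$pgs$clump_r2,
                           config$pgs$clump_window_kb)
    scz_use <- scz_h[scz_h$SNP %in% kept, ]
  }
  grid <- config$pgs$grid
  pgs_all <- score_individuals(clean, scz_use, grid, label = "all")
  pgs_con <- score_individuals(clean, scz_use, grid, split$concordant,
                               label = "concordant")
  pgs_dis <- score_individuals(clean, scz_use, grid, split$discordant,
                               label = "discordant")

  # --- phenotype: latent fast-spindle density -------------------------
  # true genetic score: dosages weighted by the generating (non-null)
  # schizophrenia effects
  truth <- ss$truth[match(clean$variants$id, ss$truth$SNP), ]
  true_eff <- log(ss$scz$OR[match(clean$variants$id, ss$scz$SNP)])
  true_eff[truth$null] <- 0
  dos_imp <- clean$dosages
  pfreq <- allele_freq(dos_imp)
  for (j in which(colSums(is.na(dos_imp)) > 0))
    dos_imp[is.na(dos_imp[, j]), j] <- 2 * pfreq[j]
  true_score <- drop(dos_imp %*% true_eff)

  n_cov_pcs <- min(config$assoc$n_covariate_pcs, ncol(pcs))
  sex_age <- with_seed(child_seed(seed, 4L),
                       data.frame(sex = sample(0:1, nrow(clean$dosages),
                                               replace = TRUE),
                                  age = stats::runif(nrow(clean$dosages),
                                                     18, 60)))
  covar <- cbind(sex_age, pcs[, seq_len(n_cov_pcs), drop = FALSE])
  model <- pheno_model(config$phenotype$target_incremental_r2,
                       covariate_effects = c(0.1, 0.005,
                                             rep(0.02, n_cov_pcs)),
                       noise_sd = config$phenotype$noise_sd)
  latent <- simulate_phenotype(true_score, covar, model,
                               seed = child_seed(seed, 5L))
  # map to the density scale of healthy adults (mean 2.22, SD 0.38 / 30 s)
  sp <- config$spindle
  latent_density <- pmax(0.2, sp$density_mean +
                           sp$density_sd * as.numeric(scale(latent)))

  # --- spindle phenotyping -------------------------------------------
  if (sp$mode == "eeg") {
    dur <- sp$epochs_per_subject * 30
    phenotype <- vapply(seq_along(latent_density), function(i) {
      sim <- simulate_eeg(dur, band = sp$band,
                          truth_density = latent_density[i],
                          amplitude_uv = sp$amplitude_uv,
                          noise_profile = list(pink = sp$noise_pink,
                                               white = sp$noise_white),
                          seed = child_seed(seed, 100L + i))
      spec <- nrem_power_spectrum(sim$recording, sim$hypnogram)
      peak <- find_spindle_peak(spec, sp$band)
      if (!peak$present) return(NA_real_)
      ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak,
                                  sp$halfwidth_hz, sp$rms_window_s,
                                  sp$threshold_sd, sp$min_dur_s, sp$max_dur_s)
      summarize_spindles(ev, sim$hypnogram)$density
    }, numeric(1))
    report$n_absent_peak <- sum(is.na(phenotype))
    keep <- !is.na(phenotype)
  } else {
    phenotype <- latent_density
    keep <- rep(TRUE, length(phenotype))
  }
  report$mean_density <- mean(phenotype[keep])

  # --- association ----------------------------------------------------
  covm <- as.matrix(covar)
  scans <- list(
    all = threshold_scan(phenotype[keep], subset_pgs(pgs_all, keep),
                         covm[keep, , drop = FALSE]),
    concordant = threshold_scan(phenotype[keep], subset_pgs(pgs_con, keep),
                                covm[keep, , drop = FALSE]),
    discordant = threshold_scan(phenotype[keep], subset_pgs(pgs_dis, keep),
                                covm[keep, , drop = FALSE]))
  report$association <- lapply(scans, function(s)
    s[, c("threshold", "incremental_r2", "coefficient_p", "n_snps", "best")])
  best_k <- which(scans$all$best)
  report$best_threshold <- scans$all$threshold[best_k]
  report$best_incremental_r2 <- scans$all$incremental_r2[best_k]
  quint <- quintile_summary(pgs_all$scores[keep, best_k], phenotype[keep])
  report$quintile_change <- quint$change

  # --- gene-based test ------------------------------------------------
  gr <- config$gene_region
  region_stats <- restrict_to_region(scz_h, gr$chrom, gr$start_bp,
                                     gr$end_bp, gr$flank_kb)
  if (nrow(region_stats) > 0) {
    region_ds <- clean
    region_ds$dosages <- dos_imp[keep, match(region_stats$SNP,
                                             clean$variants$id),
                                 drop = FALSE]
    region_ds$individuals <- clean$individuals[keep, , drop = FALSE]
    region_ds$variants <- clean$variants[
      match(region_stats$SNP, clean$variants$id), ]
    gt <- gene_based_test(region_ds, phenotype[keep],
                          covm[keep, , drop = FALSE])
    report$gene_test <- gt[c("p_value", "n_variants", "n_pcs")]
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_plink(clean, file.path(out_dir, "genotypes_clean"))
    write_sumstats_tsv(ss$scz, file.path(out_dir, "sumstats_scz.tsv"))
    write_sumstats_tsv(ss$iq, file.path(out_dir, "sumstats_iq.tsv"))
    utils::write.table(data.frame(id = clean$individuals$id,
                                  phenotype = phenotype),
                       file.path(out_dir, "phenotype.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(scans))
      utils::write.table(scans[[nm]],
                         file.path(out_dir, paste0("assoc_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_sidecar(report, file.path(out_dir, "report.json"))
    return(invisible(report))
  }
  report
}

subset_pgs <- function(pgs, keep) {
  pgs$scores <- pgs$scores[keep, , drop = FALSE]
  pgs
}
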
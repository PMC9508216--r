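#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs with known ground truth.
#
# No public cohort exists for this design (EEG + genotypes + two GWAS
# summary-statistic tables), so the analysis runs on a synthetic cohort:
# 150 individuals genotyped at 2,000 biallelic variants laid out in LD
# blocks, with two cryptically related pairs and sporadic missing calls,
# plus paired schizophrenia (odds ratio) and IQ (beta) summary statistics
# whose effect-direction concordance is 50% by construction.
#
# Writes: results/data/genotypes.{bed,bim,fam}, sumstats_{scz,iq}.tsv,
#         truth.json

library(spindlepgs)

seed <- 2026L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_gen_config(n_individuals = 150, n_variants = 2000,
                      maf_range = c(0.05, 0.5), ld_block_size = 10,
                      ld_rho = 0.3, n_related_pairs = 2,
                      missing_rate = 0.005, seed = child_seed(seed, 1L))
geno <- simulate_genotypes(cfg)
write_plink(geno, "results/data/genotypes")

ss <- simulate_summary_stats(geno$variants, concordant_fraction = 0.5,
                             effect_sd = 0.05, null_fraction = 0.2,
                             seed = child_seed(seed, 2L))
write_sumstats_tsv(ss$scz, "results/data/sumstats_scz.tsv")
write_sumstats_tsv(ss$iq, "results/data/sumstats_iq.tsv")
write_json_sidecar(list(seed = seed,
                        related_pairs = geno$related_pairs,
                        truth = ss$truth),
                   "results/data/truth.json")

cat(sprintf("cohort: %d individuals x %d variants (%d related pairs)\n",
            nrow(geno$dosages), ncol(geno$dosages),
            nrow(geno$related_pairs)))
cat(sprintf("summary stats: %d variants, %.1f%% null, concordance target 50%%\n",
            nrow(ss$scz), 100 * mean(ss$truth$null)))
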
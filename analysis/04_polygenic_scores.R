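#!/usr/bin/env Rscript
# Stage 4 — polygenic scoring at the p-value threshold grid.
#
# Schizophrenia summary statistics are info-filtered (>= 0.9), harmonized
# to the clean genotypes (palindromic A/T and C/G variants removed,
# swapped orientations resolved), and scored at PT = 0.001, 0.05, 0.1,
# 0.2, 0.3, 0.4, 0.5, 1 for three SNP subsets: all variants, and the
# schizophrenia-IQ effect-direction concordant and discordant strata
# (both scored with schizophrenia p-values and effect sizes).
#
# Reads:  results/data/*, results/qc/*
# Writes: results/pgs/pgs_{all,concordant,discordant}.tsv, pgs_meta.json

library(spindlepgs)

dir.create("results/pgs", recursive = TRUE, showWarnings = FALSE)

clean <- read_plink("results/qc/genotypes_clean")
scz <- harmonize_alleles(
  info_filter(read_sumstats_tsv("results/data/sumstats_scz.tsv")), clean)
iq <- harmonize_alleles(
  info_filter(read_sumstats_tsv("results/data/sumstats_iq.tsv")), clean)
split <- split_by_concordance(scz, iq)

subsets <- list(all = NULL, concordant = split$concordant,
                discordant = split$discordant)
meta <- list(harmonization = as.list(attr(scz, "counts")),
             n_concordant = length(split$concordant),
             n_discordant = length(split$discordant),
             n_zero_effect = length(split$zero))
for (nm in names(subsets)) {
  m <- score_individuals(clean, scz, subset = subsets[[nm]], label = nm)
  utils::write.table(
    data.frame(id = rownames(m$scores), m$scores, check.names = FALSE),
    sprintf("results/pgs/pgs_%s.tsv", nm), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meta[[paste0("n_snps_", nm)]] <- m$n_snps
  cat(sprintf("%-11s SNPs per threshold: %s\n", nm,
              paste(m$n_snps, collapse = " ")))
}
write_json_sidecar(meta, "results/pgs/pgs_meta.json")
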
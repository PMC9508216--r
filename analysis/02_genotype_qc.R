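#!/usr/bin/env Rscript
# Stage 2 — genotype quality control.
#
# Applies the full cascade in fixed order: sample missingness and
# heterozygosity filters; variant MAF (0.01), HWE exact test (1e-6) and
# missingness (0.02) filters; a stricter high-quality SNP set (HWE p >
# 0.02, MAF > 0.20, zero missingness) used only for LD pruning (r2 < 0.1,
# 200-SNP windows), relatedness exclusion (pi-hat > 0.20, one member
# removed at random) and PCA outlier screening (6 SD on 20 PCs).
#
# Reads:  results/data/genotypes.*
# Writes: results/qc/genotypes_clean.*, pcs.tsv, qc_report.json

library(spindlepgs)

seed <- 2026L
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

geno <- read_plink("results/data/genotypes")
qc <- qc_cascade(geno, seed = child_seed(seed, 3L))

write_plink(qc$dataset, "results/qc/genotypes_clean")
pcs <- qc$report$pc_matrix
utils::write.table(
  data.frame(id = rownames(pcs), pcs, check.names = FALSE),
  "results/qc/pcs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write_json_sidecar(list(
  removed_individuals = qc$report$removed_individuals,
  removed_variants = qc$report$removed_variants,
  n_pruned_snps = length(qc$report$pruned_snp_set),
  log = qc$report$log), "results/qc/qc_report.json")

cat(sprintf("QC: %d -> %d individuals, %d -> %d variants\n",
            nrow(geno$dosages), nrow(qc$dataset$dosages),
            ncol(geno$dosages), ncol(qc$dataset$dosages)))
print(table(qc$report$removed_individuals$reason))
print(table(qc$report$removed_variants$reason))
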
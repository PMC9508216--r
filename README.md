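# spindlepgs

Sleep spindle phenotyping and polygenic-score association analysis, as one
tested R pipeline.

Fast sleep spindles (12–15 Hz sigma bursts in N2/N3 sleep) are a highly
heritable EEG phenotype that is reduced in schizophrenia and correlated
with cognitive ability. A natural question is whether spindle density in
healthy adults tracks *polygenic* risk for schizophrenia, and whether that
association is carried by the subset of risk variants whose effect
direction on intelligence agrees with their effect on schizophrenia risk
(concordant variants) or by the subset where the directions oppose
(discordant variants). Answering it requires a chain of methods that
rarely live in one place:

* **Spindle detection** with individual adaptation: per-subject NREM power
  spectrum → individual sigma peak → band-pass at peak ± 1.5 Hz → 200-ms
  RMS → events where RMS exceeds 1.5 SD of the filtered signal for
  0.5–3 s; density = events per artifact-free 30-s N2/N3 epoch.
* **Genotype QC**: sample missingness/heterozygosity filters; variant MAF
  < 0.01, Hardy–Weinberg exact p < 1e-6, missingness > 0.02; LD pruning
  (r² < 0.1, 200-SNP windows) on a high-quality SNP set; relatedness
  exclusion (π̂ > 0.20); PCA outlier removal (6 SD, 20 PCs).
* **Polygenic scores** `PGS_i(t) = Σ_{j: p_j < t} dosage_ij · log(OR_j)`
  at thresholds t ∈ {0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1}, with
  allele harmonization, info-score filtering (≥ 0.9), optional clumping,
  and SCZ–IQ concordance stratification.
* **Association**: incremental R² of the score over `density ~ sex + age
  + PC1..PC10`, quintile summaries, and a principal-components-regression
  gene-based test.

No public dataset combines all the inputs, so the package also ships
simulators (EEG with embedded ground-truth bursts, HWE genotypes with LD
blocks and relatedness, paired GWAS summary statistics with configurable
effect-direction concordance, phenotypes with an exact target incremental
R²) — every stage is testable against known truth or an independent
oracle.

## Worked example

The `analysis/` scripts run the whole study on a synthetic cohort of 150
individuals × 2,000 variants, with the true genetic score explaining 5.2 %
of latent spindle-density variance:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_genotype_qc.R
Rscript analysis/03_spindle_phenotypes.R   # ~1.5 min: 148 EEG recordings
Rscript analysis/04_polygenic_scores.R
Rscript analysis/05_association.R
```

Output of the run (tables land under `results/`):

```
cohort: 150 individuals x 2000 variants (2 related pairs)
QC: 150 -> 148 individuals, 2000 -> 1984 variants
phenotyped 148/148 subjects (fast peak detectable in 148)
density 2.23 +/- 0.44 per 30 s; duration 0.69 s; peak 13.54 Hz
all         SNPs per threshold: 169 387 452 545 608 665 705 900
all         best PT 0.05   incremental R2 = 7.62%  p = 0.0005
concordant  best PT 0.3    incremental R2 = 1.95%  p = 0.0843
discordant  best PT 0.3    incremental R2 = 3.00%  p = 0.0315
phenotype change by score quintile (ref = lowest): 0.000 -0.004 0.081 0.250 0.346
gene-based test: 13 variants, 13 PCs, p = 0.9244
```

Reading this: QC dropped one member of each related pair and 16 variants;
detected density (2.23/30 s) matches the generative scale; the
schizophrenia score is clearly associated with detected spindle density
(ΔR² = 7.6 % at PT 0.05 against a generative 5.2 % — at n = 148 the
estimate is noisy), phenotype rises across score quintiles, and the
gene-based test on a region carrying no concentrated effect is null, as
it should be. With only 50 % of non-null variants concordant by
construction, both strata carry part of the signal.

The same chain is available as one call:

```r
library(spindlepgs)
report <- run_pipeline(default_pipeline_config(seed = 1))
report$association$all          # 8 thresholds x (ΔR², p, n_snps)
```

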
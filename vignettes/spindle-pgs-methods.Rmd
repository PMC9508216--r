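---
title: "Methods: from NREM sigma bursts to polygenic-score association"
author: "spindlepgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from NREM sigma bursts to polygenic-score association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlepgs)
```

# What this package computes

`spindlepgs` implements the computational chain that links a sleep-EEG
phenotype — fast sleep spindle density — to polygenic risk for
schizophrenia:

1. **Spindle phenotyping.** Individually adapted detection of sigma-band
   bursts in artifact-free N2/N3 epochs, yielding per-subject density,
   duration, amplitude and peak frequency.
2. **Genotype QC.** The standard array-data cascade: sample filters,
   variant filters, a high-quality SNP set, LD pruning, relatedness
   exclusion, PCA outlier removal.
3. **Polygenic scoring.** Allele-harmonized, info-filtered scoring at a
   grid of GWAS p-value thresholds, including stratification of variants
   by the agreement of their effect directions on schizophrenia risk and
   intelligence (concordant vs discordant).
4. **Association.** Incremental $R^2$ of each score over a covariate base
   model (sex, age, 10 genetic PCs), quintile summaries, and a
   principal-components-regression gene-based test for a single gene
   region.

No suitable public dataset combines all three input types, so the package
ships simulators for each of them with known ground truth; every stage is
validated against that truth or against independent oracles.

# Spindle detection

## The model of a spindle and of the background

Simulated NREM EEG is the sum of a $1/f$-shaped pink-noise process
(default RMS 10 µV), a white-noise floor (2 µV), and Hann-windowed
sinusoidal bursts. The Hann envelope mimics the waxing–waning morphology
of real spindles; burst frequency sits inside the requested band (fast
12–15 Hz, slow 9–12 Hz), durations are Gaussian (mean 0.82 s, SD 0.05 s,
truncated to 0.5–3 s) and onsets are placed by rejection sampling with a
1-s refractory gap so ground-truth events never merge. Event counts are
Poisson with mean `density × n_epochs`. Defaults follow the spindle
statistics of healthy adults (density 2.22/30 s fast, 1.50/30 s slow;
amplitudes ≈ 28 µV; peaks 13.46 and 10.84 Hz).

What the simulator does **not** emulate: non-stationary background
(sleep-stage transitions, slow oscillations, K-complexes), amplitude
variability across events within a subject, multi-channel topography, and
real artifacts. Passing the recovery tests therefore shows the detector is
correct *given its signal model*, not that it matches human scorers on
real polysomnography.

## The detector

For each subject, an averaged Hann periodogram over all included 30-s
epochs (resolution 1/30 Hz) is searched for the individual spindle peak.
The spectrum is smoothed over ≈0.25 Hz, a log–log linear background is
fitted outside 8.5–16 Hz, and the most prominent in-band local maximum is
taken. A peak counts as detectable only when it rises at least
**2-fold** above the fitted background. A weaker rule (e.g. 10 % above
background) flags peaks in pure-noise spectra — epoch-averaged
periodograms of 10–40 epochs show chance in-band bumps of 1.2–1.75× —
whereas the weakest genuine peaks in our simulations (density 1/30 s)
reach ≈2.6×; the 2× criterion separates the two regimes and stands in for
the visual call "a clearly visible bump". An absent peak is a legal state:
such subjects are excluded from that band's analysis, never zero-filled.

Detection then band-pass filters the signal at peak ± 1.5 Hz (4th-order
Butterworth, forward–backward so event timing is phase-preserved),
computes RMS over consecutive non-overlapping 200-ms windows, and marks
events as runs of windows whose RMS exceeds 1.5 SD of the filtered signal
(SD over included epochs), lasting 0.5–3 s. Numerical details that matter:

* At 256 Hz a 200-ms window is 51 whole samples (0.19922 s); onsets and
  durations are reported in true sample time. (Reporting on a nominal
  0.2-s grid drifts by ≈0.8 s over four minutes.)
* Duration is the distance between threshold crossings of the step-wise
  RMS series, so it is quantized to one window; a 1.0-s burst typically
  reads as 0.8–1.0 s. Detected durations are systematically *shorter*
  than generative durations (the envelope tails sit below threshold):
  with the default SNR, 0.82-s bursts read ≈0.68 s on average.
* Runs longer than 3 s are discarded entirely (strict reading of the
  duration rule), not truncated.
* Supra-threshold runs are not merged across sub-200-ms gaps.
* An event is assigned to the epoch containing its onset; events touching
  an excluded epoch are dropped.
* The threshold SD is computed over the filtered signal; a config switch
  (`threshold_on = "rms"`) uses the RMS series instead, since the original
  description is ambiguous. A single per-subject threshold covers N2 and
  N3.

Because the threshold is *relative* (1.5 SD of the filtered signal,
bursts included), it tracks burst amplitude once bursts dominate the
band variance; in the infinite-amplitude limit the supra-threshold runs
shrink below the minimum duration. Recovery is therefore quantified over
a finite SNR grid (burst amplitude 3–10× the broadband background SD,
densities 1–3/30 s), where the median relative density error is far below
the 15 % design bound and at the top of the grid recall is 1 with a
negligible false-event rate.

# Genotype simulation and QC

Haplotypes are thresholded from a block-diagonal Gaussian copula: within
an `ld_block_size` block the latent normals share correlation `ld_rho`,
giving LD while preserving exact Hardy–Weinberg marginals at each
variant's MAF; genotypes are the sum of two haplotypes. Cryptic
relatedness is created by copying one haplotype between pair members
(expected $\hat\pi \approx 0.5$, parent–offspring-like). There is no
mutation/recombination/demography model — LD decay with distance,
allele-frequency spectra and population structure are not realistic, which
is why PCA-outlier behaviour is exercised with constructed contaminants
rather than simulated admixture.

The QC cascade runs in fixed order: sample missingness (> 0.02) and
normalized heterozygosity deviation (|obs − exp|/exp > 0.2, computed on
the high-quality set; the PLINK-style convention), then variant MAF
(< 0.01), HWE exact p (< 1e-6) and missingness (> 0.02); pruning,
relatedness ($\hat\pi$ > 0.20, one member removed at random under the
stage seed) and PCA (outliers beyond 6 SD on any of 20 PCs, with one
re-fit after removal so outliers do not define the covariate axes) all
operate on the high-quality pruned set. Sex-mismatch checking is a logged
no-op: no sex chromosomes are simulated. Heterozygosity is computed on
the high-quality set (the cascade's first pass over a fresh dataset);
computing it before vs after variant QC is a documented config choice.

Re-running the cascade on its own output removes nothing further —
*provided* no statistic sits exactly on a threshold: removing individuals
changes the denominators of per-variant missingness and MAF, so a variant
at, say, 2/100 missing calls can cross the 0.02 boundary when the cohort
shrinks to 99. This boundary sensitivity is intrinsic to threshold-based
QC, not an implementation artifact.

The HWE exact test sums conditional heterozygote-count probabilities no
more probable than the observed one (two-sided), via the standard
recurrence; tests verify it against a direct log-factorial enumeration
oracle at 1e-12. Its p-value is discrete and conservative, so calibration
against Uniform(0,1) is checked on the **mid-p** variant
(`hwe_exact_test(..., midp = TRUE)`); QC filtering uses the conservative
p-value.

LD pruning is greedy within 200-variant windows sliding by 50 (the
window size is standard; the step is our choice), dropping the
lower-MAF member of each offending pair (tie: later position) until all
within-window pairs satisfy $r^2 < 0.1$.

# Polygenic scores

Harmonization matches variants by ID and resolves allele orientation.
Effects stay expressed per copy of the summary-statistics effect allele
(odds ratios log-transformed first — additivity requires the log scale);
a flip flag records when the genotype file stores the complementary
orientation, and scoring counts effect-allele copies as `2 − dosage`
there. This makes scores exactly invariant to how either side stored the
allele pair (bit-identical on complete data; mean-imputed missing calls
agree to 1 ulp). Palindromic A/T and C/G variants are always removed —
neither simulated nor typical real `.bim` files carry strand information.

Missing dosages are mean-imputed as twice the cohort allele frequency
(keeps scores comparable across individuals; the GWAS frequency is not
available in general). Thresholding is strict (`p < t`). Clumping
(greedy, best-p index variants, defaults r² 0.1 / 250 kb) is available
but off by default: whether the original scoring used clumping is not
stated, so both modes are supported and logged.

The concordant/discordant stratification intersects the schizophrenia and
IQ tables after re-orienting the IQ effect to the schizophrenia table's
effect allele, then partitions non-null shared variants by sign
agreement of log(OR) and beta. Zero effects belong to neither stratum —
direction is undefined at zero. Both strata are scored with the
schizophrenia p-values and effect sizes. In the generator the concordance
indicator is Bernoulli per non-null variant, so realized splits follow
binomial bounds around the configured fraction.

# Association

Incremental $R^2$ is the increase in the ordinary (unadjusted)
coefficient of determination when the score joins the base OLS model
(sex + age + PC1..PC10); the coefficient p-value is the two-sided t-test.
The exact algebraic identity used as an oracle is
$\Delta R^2 = (1 - R^2_{base}) \cdot r^2_{partial}$, with
$r_{partial}$ the correlation of the two covariate-residualized vectors;
the popular shorthand "ΔR² equals the squared partial correlation" holds
only when the covariates explain nothing. A score collinear with the base
design yields ΔR² = 0 with p = 1 rather than an error. The threshold scan
reports every threshold and flags the maximum-ΔR² row (ties by smaller
p); no multiple-testing correction is applied across the 8 thresholds,
mirroring common practice — the permutation experiment in the tests
documents the resulting optimism, and a permutation p-value can be
computed from the same machinery by the user.

The phenotype simulator inverts the variance decomposition: given
covariate effects, noise SD and a target ΔR², the score coefficient is
$\gamma = \sqrt{R^2 (V_{cov} + \sigma^2) / (V_{s|cov}(1 - R^2))}$
using sample variances, so the population increment matches the target
(estimates carry the usual small positive OLS bias ≈ $(1-R^2)/(n-k)$).
In the noiseless, covariate-free limit the score passes through and
ΔR² = 1 exactly.

The gene-based test residualizes phenotype and standardized region
dosages on the covariates, retains principal components of the genotype
residuals explaining ≥ 99.9 % of variance (the conventional PC-pruning
cutoff; exposed as `var_retain`), and F-tests their joint fit with the
covariate rank removed from the error degrees of freedom. With one
variant it reduces exactly to the covariate-adjusted single-SNP F-test;
under the null its type-I error at 0.05 is within [0.035, 0.065] over
2,000 simulations.

Quintiles use stable ranking (ties keep input order), group sizes differ
by at most one, and changes are referenced to the lowest-score group.

# Pipeline and reproducibility

`run_pipeline()` chains the stages in the analysis order with one global
seed fanned out to per-stage child seeds (`child_seed()`, a fixed affine
map), so any stage can be reproduced in isolation and two runs with the
same config are identical apart from the report timestamp. Defaults in
`default_pipeline_config()` carry the analysis parameters above; the
simulation sizes (150 individuals, 2,000 variants, 10 N2 epochs per
subject) keep a full run around ten seconds while leaving every stage
non-trivial. The `analysis/` scripts run the same chain at 60 epochs per
subject, where spindle-detection noise attenuates the generative 5.2 %
increment only mildly.

One practical caveat the workflow makes visible: the association target
is injected into the *latent* spindle density, but the analysed phenotype
is the *detected* density. Detection noise scales as
$\sqrt{\text{density}/n_{epochs}}$ per subject, so short recordings
attenuate ΔR² substantially (at 10 epochs the measurement noise SD
≈ 0.47 exceeds the between-subject SD 0.38); with 60+ epochs the
attenuation is modest. Real studies with full-night recordings sit in the
favourable regime.

# Known limitations

* The EEG model is stationary N2 with a single channel; hypnograms and
  artifact flags are inputs, not outputs.
* Genotype simulation has no demography; relatedness is one fixed
  sharing pattern.
* Summary-statistic p-values are drawn from fixed distributions, not
  derived from a simulated GWAS, so p-value/effect-size joint structure
  is only qualitatively realistic.
* The EDF writer/reader handles exactly one channel with 1-s records —
  enough to round-trip the simulator's output, not a general EDF
  implementation.
* Scores, QC and the gene test assume autosomal biallelic variants.
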
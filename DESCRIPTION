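Package: spindlepgs
Title: Sleep Spindle Phenotyping and Polygenic Score Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, fully synthetic-data-testable pipeline linking
    fast sleep spindle density from NREM EEG to polygenic risk for
    schizophrenia. Implements individually adapted sigma-peak spindle
    detection (band-pass around each subject's spectral peak, 200-ms RMS
    windows, 1.5-SD threshold, 0.5-3 s duration rule), a genotype
    quality-control cascade (sample and variant filters, Hardy-Weinberg
    exact test, LD pruning, relatedness exclusion, principal-component
    outlier removal), p-value-threshold polygenic scoring with allele
    harmonization and stratification of variants into schizophrenia-IQ
    effect-direction concordant and discordant subsets, incremental-R2
    covariate-adjusted association with quintile summaries, and a
    principal-components-regression gene-based test. Simulators for EEG,
    genotypes, GWAS summary statistics and phenotypes with known ground
    truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
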
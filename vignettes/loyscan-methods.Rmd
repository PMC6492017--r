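---
title: "Detecting mosaic loss of the Y chromosome from segmented copy-number data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic loss of the Y chromosome from segmented copy-number data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyscan)
```

## The problem

Mosaic loss of the Y chromosome (LoY) is the most common somatic structural
variant in aging men and has been linked to increased cancer risk and
shorter survival. In a tumor cohort profiled with SNP arrays, LoY shows up
as a depressed average copy number over the Y chromosome — but two effects
push the observed value away from the naive expectation of 0: a tumor
sample is a mixture of tumor and normal cells (purity), and the loss itself
is often carried by only a subpopulation of tumor cells (subclonality).
`loyscan` implements the full analysis path from segmented copy-number data
to LoY calls and their clinical correlates: copy-number indices, bimodal
classification, an aneuploidy score, expression-based confirmation,
filtered differential expression with gene-set enrichment, and survival and
association statistics.

## The copy-number model

All indices live on a **linear** copy-number scale where a diploid autosome
is 2 and a single Y copy is 1. SEG segment means in the SNP-array
convention are `log2(CN / 2)` and are converted with `2 * 2^v` before any
averaging (`to_linear_cn()`); averaging in log space would bias the index
low on heterogeneous arms, and the linear scale is what makes the observed
LoY and retained modes interpretable as copy numbers.

The **arm index** is the overlap-length-weighted mean copy number of all
segments intersecting an arm, after masking exclusion intervals
(`arm_index()`). The **Y index** is the same average over the
male-specific region: both Y arms with the two pseudoautosomal regions
(PARs) removed, since the PARs are shared with X and are not covered by
Y-specific probes. The **total autosomal aneuploidy index** is
`sum(|2 - index|)` over autosomal arms, excluding the short arms of the
acrocentric chromosomes 13, 14, 15 and 22, which carry no array coverage.
21p is also acrocentric but is included by default
(`genome_arms(include_21p = FALSE)` reverses that choice); the packaged arm
table is cytoband-derived GRCh37/hg19.

Observed indices are corrected for tumor purity with the two-component
mixture model

\[ \text{observed} = p \cdot \text{CN}_\text{tumor} + (1 - p) \cdot
\text{CN}_\text{normal}, \]

solved for the tumor copy number and floored at 0 (`purity_adjust()`), with
normal copy number 1 for the male Y and 2 for autosomes. The source data
state only that indices were purity-adjusted; this deconvolution is the
standard choice and is exactly invertible on noiseless mixtures (a tested
invariant). Purity comes from the clinical `tumor_nuclei_percent`. Samples
with missing purity keep their unadjusted index and are flagged, rather
than dropped — availability gaps in clinical tables should not silently
shrink the cohort. Note the adjustment cannot remove subclonality: if only
a fraction *f* of tumor cells lost the Y, the adjusted index converges to
`1 - f`, not 0, which is why real LoY peaks sit near 0.5 rather than 0.

## Bimodal classification

Across a male cohort the Y index is bimodal: a lower mode (LoY cases) and a
mode near 1 (retained). `fit_bimodal()` fits a Gaussian kernel density
(Silverman's rule by default, 512-point grid padded 10% beyond the data
range) and reports the two highest local maxima separated by at least
`min_separation` (default 0.2 on the copy-number scale). Both knobs are
surfaced because the peak positions depend on them; a unimodal density is a
typed error carrying the single mode, and the pipeline skips such strata
with an annotation rather than failing.

`classify_loy()` uses the peak positions themselves as cut points, per the
source analysis's "left of the first peak / right of the second peak"
language: `LOY` strictly below the lower peak, `RETAINED` strictly above
the higher peak, `UNCERTAIN` in between. Values exactly at a peak are
`UNCERTAIN` — the conservative reading of an unstated tie rule. The wide
uncertain band is a feature: downstream survival and expression contrasts
compare only the confident tails, mirroring the source design. An
antimode-based cut would call more samples but is deliberately not the
default, because the peak-based rule is the one the downstream statistics
were designed around.

For array cohorts without copy-number data, `expression_ratio()` rescales
each sex-discriminating probe so that the female mean (pure background) is
0 and the male-normal mean is 1, and `pc_loy()` combines the probes by the
first principal component of the centered (unscaled — the ratios already
share a scale) ratios, oriented so male normals score positive. The PC1
scores are then fed through the same bimodal fit and classification.

## Expression analyses

Counts are normalized to CPM with plain library sizes or TMM factors
(`cpm_normalize()`); TMM uses the standard 30%/5% doubly trimmed, precision
weighted mean of log ratios against an upper-quartile-matched reference.
`y_gene_screen()` reports genes whose Spearman correlation with the Y index
exceeds 0.5 — on real data this recovers the Y-linked dosage-sensitive
genes.

`de_test()` implements the filtering contract of the source analysis: fold
change of at least 1.5 on group-mean CPM (0.5 pseudo-count), raw p below
the stratum threshold (0.01 for HPV-negative, 0.05 for HPV-positive
contrasts), and CPM above 1 in at least as many samples as the smaller
group. The per-gene statistic is a Welch t on `log2(CPM + 0.5)` (a
Wilcoxon alternative is provided). The original analysis used edgeR / LIMMA
defaults; reproducing those estimators is out of scope and the exact gene
lists are not an acceptance surface — the filter semantics are. No
multiple-testing correction is applied inside `de_test()` (the source
filtered on raw p plus the fold-change and expression floors);
Benjamini-Hochberg adjustment is applied only across terms in `enrich()`,
the hypergeometric gene-set stand-in for the original web-service ontology
analysis, whose fold-enrichment column is `(k/n)/(K/N)`.

## Survival and association statistics

`km_estimate()`, `logrank_test()` and `cox_fit()` are thin, contract-tested
wrappers over the `survival` package (product-limit estimator, k-group
log-rank, partial likelihood with Efron tie handling and Wald tests) —
the same ecosystem the source analysis used. `fisher_exact()` is
implemented directly: two-sided p by the minimum-likelihood convention,
summing the probabilities of all margin-fixed tables no more probable than
the observed one; it is verified against full enumeration for every 2x2
table with total at most 40. Wilcoxon uses the exact null distribution when
both groups have at most 25 observations and no ties, otherwise the
tie-corrected normal approximation. Survival times are in days; groups with
fewer than 2 samples are dropped from KM / log-rank with a warning; the
age median split assigns ties to the lower group.

## The synthetic cohort

`simulate_cohort()` generates the stated world every test runs against:

* `n_samples = 500`, `female_fraction = 0.27` — the shape of the real
  cohort (369 male / 135 female).
* `loy_prevalence = 0.25` — LoY detectable in about a quarter of males.
* purity `Beta(8, 2)` (mean 0.8), emitted as `tumor_nuclei_percent`.
* `subclonal_loy_fraction = 0.5`: each LoY sample draws its cell fraction
  `f_i` from `Beta(8f, 8(1-f))`. The mean 0.5 is chosen because the
  purity-adjusted LoY index converges to `1 - f`, so the two modes sit at
  0.5 and 1.0 — the positions reported for the real data. The per-sample
  spread gives the continuous Y-dosage variation that real cohorts show
  (a broad LoY shoulder, and Y-gene/index correlations well above the
  binary-label ceiling of `3 * pi * (1 - pi)`). The within-tumor LoY cell
  fraction is not reported by the source study; 0.5 is this package's
  choice, fixed once, not an estimate of the real cohorts.
* arm events: Poisson with mean 10 (LoY) vs 5 (non-LoY) gains/losses of a
  full tumor copy — LoY tumors are more aneuploid by construction.
* `segment_noise_sd = 0.05` on linear segment means; segments are emitted
  as log2 ratios by default. Female samples carry **no** Y rows, matching
  real SEG emissions, so the Y-index code must (and does) tolerate absent
  Y coverage.
* survival: exponential event times at `5e-4`/day baseline, hazard ratio 2
  for LoY, independent exponential censoring at the same rate (about half
  the cohort censored — typical of an observational tumor registry).
* counts: negative binomial, dispersion 0.05 (BCV ~0.22, a well-controlled
  bulk cohort), gene means log-normal around 50 with 19 well-expressed
  Y-linked dosage genes (means around 200, proportional to the purity-mixed
  Y copy number and zero in females), 100 immune genes scaled by
  `2^(-1 * aneuploidy percentile)` and 40 redox genes scaled by `2^(+1)`
  in LoY samples. The percentile-rank scaling makes `immune_log2fc` the
  approximate realized top-vs-bottom-tercile contrast.
* all randomness flows from one root seed through named substreams
  (clinical, segments, counts, array), so identical configs are
  byte-identical and blocks can be regenerated independently.

`simulate_microarray()` emulates the array side: probe intensities are
background plus signal proportional to Y dosage (`1 - f_i * purity` for LoY
tumors), with noise at 10% of the signal by default.

What a green test does **not** establish: the generator has no GC waves, no
probe-level noise structure, no segmentation artifacts, no correlated
clinical confounding (beyond the configured smoking/pathologic-T/LoY
links), no multi-clone architecture, and far fewer genes (2,000 by default,
purely for test runtime) than a real expression matrix. Passing tests show
the algorithms are correct under the stated model, not that the model
captures everything real SNP6/RNA-seq data do.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; SEG I/O converts
  from/to the 1-based inclusive file convention.
* `purity_adjust` rejects purity 0 (nothing is identifiable) and floors
  adjusted values at 0.
* Arms with no overlapping segment get an absent (NA) index, not an error;
  arms covered on less than half their masked length are counted as
  low-confidence but still used — the source applied no coverage filter.
* `fit_bimodal` requires at least 20 finite values; peak search uses
  strict increase on the left and non-strict on the right to handle grid
  plateaus deterministically.
* Duplicating the full input changes Silverman's bandwidth (it depends on
  n), so exact duplication-invariance of the fit holds under a fixed
  numeric bandwidth; under the default rule it holds approximately.
* Aneuploidy terciles use stable rank order (ties broken by sample order)
  with `floor(n/3)` samples in each tail, computed per stratum.
* Zero-variance genes with equal means get p = 1 in `de_test`, and probes
  whose male-normal adjusted mean is non-positive are dropped from
  expression ratios with a warning.

## Known limitations

* Whether the original analysis excluded 21p, and whether it averaged in
  linear or log space, is not stated; both defaults here are configurable
  and documented above.
* The exact density estimator and bandwidth behind the published peak
  positions are unstated, so peaks reproduce approximately (0.48/1.01 for
  HPV-negative data), not to the third decimal.
* The DE statistic is a filtering contract, not an edgeR/LIMMA
  re-implementation; published gene-list membership is not expected to
  reproduce exactly.
* No allele-specific copy number, GC correction, re-segmentation, or
  model-based purity/ploidy estimation: the SEG file and the clinical
  purity column are taken as given.
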
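---
title: "Methylation-based tumor classes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based tumor classes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `methylscope`, the parameters
that matter and their defaults, what the synthetic-cohort generator does
and does not emulate, and the choices made where the underlying methodology
left the design genuinely open. It states no empirical result beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## The analysis in one paragraph

A cohort of tumors profiled on methylation arrays is summarised as a
probes × samples matrix of beta values (methylated fraction, in [0, 1])
plus a probe annotation (genomic position, CpG-island relation, genomic
region, platform membership, exclusion flags). The pipeline (i) merges
platforms on the probe intersection and removes unreliable probes, (ii)
discovers sample classes by hierarchical clustering of the most variable
probes, (iii) infers copy-number segments from total array intensity and
condenses each genome's complexity into the genomic index, (iv) quantifies
global and stratified methylation levels, (v) calls differentially
methylated probes and regions between classes, and (vi) compares clinical
covariates and survival across classes. All containers are Bioconductor
types: a `MethylCohort` extends `RangedSummarizedExperiment`; segments,
DMRs and annotations are `GRanges`.

## The synthetic-cohort generator

No public generative model exists for this kind of cohort, so the package
defines one with direct control over every quantity the downstream stages
estimate. Betas follow a clamped-normal model

$$\beta_{ps} = \mathrm{clamp}_{[0,1]}\!\big(\mu(\mathrm{class}(s),
\mathrm{context}(p)) + d_p + \varepsilon_{ps}\big),$$

where $d_p \sim N(0, 0.10)$ (open sea) or $N(0, 0.07)$ (CpG island) is a
shared per-probe baseline deviation producing the familiar bimodal beta
distribution, and $\varepsilon_{ps} \sim N(0, 0.04)$ is measurement noise.
A clamped normal was chosen over beta-distribution draws because the class
means — the quantities recovery tests check — enter the model directly.
Clamping introduces a small upward bias for island probes (target mean
0.15 with combined SD ≈ 0.08 puts ~3% of mass below zero); this is
irrelevant to every test, which compares strata or classes under the same
clamping.

The default study conditions (`defaultClassSpecs()`) encode three classes:

| parameter | LG | SARC | PIS | meaning |
|---|---|---|---|---|
| open-sea mean beta | 0.60 | 0.52 | 0.45 | graded global hypomethylation |
| CNV rate (segments/sample) | 1 | 5 | 10 | graded genomic complexity |
| chr8 whole-gain probability | 0.05 | 0.85 | 0.30 | recurrent gain concentrated in the intermediate class |
| gain hypomethylation shift | 0.08 | 0.08 | 0.08 | extra beta decrease inside gains |
| DMR blocks × delta | 5 × +0.20 | 10 × −0.25 | 15 × −0.30 | clustered class-specific signal |
| PFS hazard (/month) | −ln(0.909)/60 | −ln(0.475)/60 | −ln(0.262)/60 | exponential hazards matching 5-year event-free fractions of ~91/48/26% |
| female fraction | 9/20 | 29/38 | 15/28 | clinical sex imbalance |

Copy segments are drawn per sample (count ~ Poisson(rate), gain/loss with
equal probability, rejection sampling keeps them non-overlapping), and add
±0.3 to the log2 copy signal — deliberately well clear of the ±0.1 calling
thresholds so that state-calling recovery is a well-posed question. The
per-probe log2 noise SD defaults to 0.10; real arrays are noisier per
probe, which is why practical tools average probes into bins, but at desk
scale the lower noise keeps the segmentation task informative rather than
trivially impossible. Total intensities are
$I_{ps} = b_p \cdot 2^{\ell_{ps}}$ with a shared log-normal per-probe
baseline $b_p$, and the generator also emits a small flat-genome reference
panel (8 profiles) because copy-ratio computation requires an explicit
reference.

The reduced genome is the human karyotype scaled down tenfold with ~20k
probes standing in for 450k/850k scale (all statistics downstream are
scale-free). Sex chromosomes carry probes but no class, copy or block
signal — they exist so the exclusion filter has real work. The generator
does **not** emulate batch effects, tumor purity, cell-type composition or
raw two-channel intensities; passing recovery tests therefore demonstrates
algorithmic correctness under the stated generative model, not robustness
to those real-data phenomena.

## Preprocessing

Platform merging keeps exactly the probe intersection and all samples.
Probes are removed, in a fixed reporting order (sex chromosome, SNP
overlap, multi-hit, non-unique mapping), with a probe failing several
rules attributed to the first — the removal outcome is order-independent,
only the report depends on the order. The pipeline ingests normalised
betas; raw-intensity normalisation is upstream of this package. Because
variance ranking and per-probe t-tests need complete rows, probes with
missing values are dropped before clustering and testing
(`dropIncompleteProbes()`, threshold configurable); this missingness policy
is a package decision, not an inherited one. The beta→M transform is
provided as a convenience (`M = log2((β+ε)/(1−β+ε))`); all shipped
analyses operate on betas.

## Class discovery

"Most variable" is implemented as largest per-probe standard deviation of
beta, the common convention for methylation classifiers, with ties broken
lexicographically by probe id so selections are deterministic and nested.
Both average and Ward linkage are supported — method descriptions and
figure legends in this literature disagree on which is used — and the
default is average linkage; the class-recovery tests check that the
desk-scale conclusion is linkage-invariant. The number of classes `k` is a
user input: published class systems are fixed by expert inspection, and the
package claims no automatic model selection. t-SNE runs the exact
O(n²) algorithm (cohorts here are tens to hundreds of samples) with
perplexity min(30, (n−2)/3), 1000 iterations, learning rate 100, early
exaggeration 12×, and a seeded random initialisation: reproducibility is
prioritised over fidelity to any particular library default, and the
contract is neighbourhood preservation, never specific coordinates.
Cluster stability is a bootstrap over probes: a sample is stable in a
replicate when it co-clusters with the majority of its original cluster.

## Copy-number inference

Log2 ratios are `log2(intensity / per-probe reference median)`,
median-centred per sample. Segmentation is a recursive binary procedure
defined by the package (self-contained and oracle-testable, in contrast to
the black-box segmenters common in this space): within each chromosome the
candidate split maximising the two-sample Welch t statistic is accepted iff
the mean difference is ≥ `min_delta` (default 0.1), the t-distribution
p-value survives Bonferroni correction over candidate positions at `alpha`
(default 0.01), and both children retain ≥ `min_probes` (default 5);
accepted children recurse. Segment means are member-probe means, so the
probe-count-weighted mean of segment means reconstructs the profile mean
exactly.

States are called by strict exceedance of ±0.1 log2 — a segment mean equal
to a threshold is balanced. The genomic index is A²/C with A the gained
plus lost segment count and C the distinct chromosomes carrying them; a
fully balanced genome (A = 0, where the ratio is 0/0) is defined as GI = 0,
and whole-chromosome alterations count as one segment on one chromosome.
Sex chromosomes are filtered upstream, so the index effectively covers
autosomes. Focal amplifications/deletions — identified by manual review in
practice — get an automated surrogate with declared thresholds (|log2| > 1,
length ≤ 2 Mb on the reduced genome). SEG export uses the 1-based inclusive
convention of that format; BED exports are 0-based half-open.

## Methylation quantification and cohort statistics

Global means exclude CpG-island probes by default: island CpGs sit near
zero regardless of genome-wide state and would dilute a hypomethylation
signal. The same switch applies to copy-state-stratified means and is
recorded in the output's attributes. Strata with no probes yield flagged
`NA`, never 0. Promoter/body strata come from the annotation's region
field; no TSS-distance inference is attempted.

Chi-squared tests are Pearson, without continuity correction, with
p-values reported both at full precision and rounded to three decimals
(the reporting convention for clinical tables). Games–Howell pairwise
comparisons use Welch–Satterthwaite degrees of freedom and the studentized
range distribution at $q = |t|\sqrt{2}$, computed with R's `ptukey`. Note
that Games–Howell is a familywise procedure: under a complete null the
probability that *any* pair rejects is the nominal 5%, while each single
pair rejects less often. The calibration test therefore checks the
family-wise rejection rate against 0.05 ± 2 SE.

## Differential methylation

The per-probe test is Welch's t on betas (vectorised across probes and
cross-checked against `t.test`), with BH adjustment and significance at
FDR < 0.05. Whether to test betas or M-values, and with which statistic,
is not standardised in this literature; Welch-on-beta is this package's
recorded choice, keeping the significance semantics (BH, FDR < 0.05)
unchanged. Delta bands are open at ±0.1: a delta of exactly 0.1 is "mid".
Delta orientation is `mean(second group) − mean(first group)`; the caller
fixes which class is baseline.

The probe-lasso DMR caller uses a single configurable radius (default
1000 bp) rather than feature-specific density-scaled windows: the pinned
rule is "≥ 5 significant probes per lasso, adjusted p < 0.05", and the
fixed-radius variant implements exactly that rule in a form a brute-force
sliding-window oracle can verify. Retained lassos merge when they share at
least 1 bp; merged regions are trimmed to their outermost member
significant probes, so every significant probe inside reported bounds is a
member. Regions whose member deltas average exactly zero are discarded
(direction would be undefined). Cross-class DMR intersection requires ≥1 bp
overlap *and* matching direction sign.

Gene-set enrichment is the one-sided hypergeometric upper tail against the
annotation's full gene complement, BH-adjusted across sets; gene sets are
read from GMT. The hypergeometric test is discrete, hence conservative at
coarse overlap granularity; the null-calibration test runs a configuration
(universe 3000, sets of 400, queries of 600) fine-grained enough for the
attainable size to sit near the nominal 5%.

## Survival

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package behind this package's interface; the log-rank test is
the field-standard companion of KM curves where the comparison test is
otherwise unnamed. Censored subjects at an event time remain at risk for
that event (standard convention). Greenwood standard errors and
log-transform confidence intervals are clipped to [0, 1]. With no events
at all the comparison is undefined and `logrankTest` returns p = 1 with a
flag rather than an error, so cohort sweeps do not abort. Median survival
is the first observed time with S(t) ≤ 0.5, NA (reported as "not reached")
otherwise.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run the default conditions on
a 4000-probe reduced genome with 30 samples per class — the package's
chosen desk-scale configuration; all statistics involved are scale-free,
and smaller cohorts (1000–2000 probes) are used for oracle comparisons and
multi-seed sweeps. Degenerate inputs are handled explicitly: zero-variance
probes get p = 1 (equal means) by convention; zero-variance groups are
errors in Games–Howell and Pearson correlation; segment boundary values
equal to a calling threshold are balanced; empty strata are flagged NA.
Every stochastic component (generator, bootstrap, t-SNE initialisation) is
driven by an explicit seed, and a fixed seed fixes every output byte.

## Known limitations

* The generator's independence assumptions (probe-wise independent noise,
  no spatial autocorrelation outside the planted blocks) make DMR recovery
  easier than on real arrays, where correlated probes inflate regional
  false positives.
* The segmentation criterion tests each split at a Bonferroni-corrected
  level but does not control a genome-wide error rate across the recursion.
* The genomic index depends on segmentation granularity; absolute values
  are comparable only within one pipeline configuration, which is why
  cross-class *ordering*, not absolute medians, is the tested property.
* Survival simulation is exponential with independent censoring; no
  competing risks, no Cox modelling.
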
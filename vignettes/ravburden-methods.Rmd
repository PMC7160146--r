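---
title: "Methods: ultra-rare variant and structural-variant burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultra-rare variant and structural-variant burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ravburden implements a case-control whole-genome sequencing (WGS) analysis
of rare genetic variation of the kind used to study schizophrenia and other
complex psychiatric disorders: quality control of jointly-called SNV/indel
and structural-variant (SV) genotypes, classification of ultra-rare
variants against external population references and functional annotations,
covariate-adjusted logistic burden tests with permutation support,
single-variant association, analytic power, and MAF/LD-stratified GREML
heritability. This vignette records the models, the parameter choices that
matter, and the design decisions taken where the methodology was genuinely
open.

## The scientific setting

Cohorts of this design contain on the order of a thousand cases and a
thousand ancestry-matched population controls with ~30-40x WGS. Two variant
classes carry the main analyses:

* **Ultra-rare variants (URVs)**: SNVs/indels seen exactly once in the
  cohort (a singleton heterozygote) *and* absent (allele count 0) from
  external population references (e.g. gnomAD genomes and a non-psychiatric
  exome reference). Absence is required from every configured source; a
  single external observation disqualifies the variant.
* **Ultra-rare SVs**: deletions (DEL), tandem duplications (DUP) and
  inversions (INV) occurring once in the cohort and absent from SV
  population databases, where "absent" means that no same-type database
  variant covers 30% or more of the query SV (the query SV length is the
  denominator, following SV-annotation convention).

Burden testing asks whether cases carry more qualifying variants than
controls inside an annotation of interest — coding consequence classes,
constrained noncoding sequence, brain epigenomic annotations, and notably
the 40-kb bins that form boundaries of topologically associating domains
(TADs), where disruption is expected to dysregulate local gene expression.

## Quality control

`qc_thresholds()` holds the filter settings; defaults follow deep WGS
case-control practice:

* genotypes with depth DP < 10 or quality GQ < 20 are set missing (both
  boundaries inclusive on the keep side);
* variants are removed, in order, when monomorphic; missing in more than 2%
  of samples; differentially missing between cases and controls (rate
  difference > 0.02, or two-sided Fisher exact p < 0.005 on the
  called/missing x case/control table); or out of Hardy-Weinberg
  equilibrium. HWE p-values come from the exact conditional test
  (`hwe_exact_test()`, probability-mass ordering, not mid-p), are computed
  separately in controls and in cases over all variants reaching the
  filter, BH-adjusted within stratum, and thresholded at FDR 1e-6
  (controls) / 1e-10 (cases). The much stricter case threshold avoids
  discarding genuine association signal, which distorts case genotype
  frequencies.
* pairs of samples with method-of-moments relatedness pi-hat > 0.2 lose one
  member (0.05 for heritability estimation). `estimate_relatedness()` uses
  the classic IBS-moment estimator on common (MAF >= 0.05), LD-thinned
  variants; pruning is greedy by over-threshold pair count with ties broken
  by higher missingness, then lexicographic sample id, so results are
  reproducible.
* samples with an outlier total URV count are pruned (strictly above 6000
  at the ~4250 mean URV scale of a full cohort). The threshold is
  scale-specific, so `qc_thresholds(urv_outlier_threshold = NULL, mean_urv =
  ...)` rescales it proportionally for synthetic cohorts. The outlier tail
  in real data is ancestry-driven; the generator emulates it with a
  configurable outlier fraction and rate multiplier plus a pseudo-PC
  correlated with outlier status (a stand-in, not a model of population
  structure).
* SVs are removed when the *union* of blacklist intervals (assembly gaps,
  segmental duplications, somatic V(D)J regions) covers strictly more than
  66% of the SV; two disjoint blacklist hits of 40% and 30% therefore
  remove an SV.

## Variant classification

Consequence classes (synonymous, missense non-damaging, missense damaging,
loss-of-function, noncoding) are *consumed as inputs*, as produced by an
upstream annotation tool; the package never recomputes them. Constrained
sequence is defined as mean CDTS percentile < 1 over the spanned 10-bp bins
(multi-base variants average across bins) OR GERP >= 4 at the site; for
multi-base variants GERP aggregates by maximum (conservative toward
inclusion; mean available). Promoters are 2 kb upstream of each TSS,
strand-aware. The extended gene region spans 35 kb upstream of the most
distal TSS to 10 kb downstream of the most distal transcription *end* site:
the flank description is ambiguous as usually printed (it repeats
"transcription start site"), and this is the only geometry that yields an
interval containing the gene; both flanks are configurable.

SV coding status follows breakpoint logic for inversions: coding iff a
breakpoint falls in a coding exon, or the breakpoints sit in two different
introns of one gene with a coding exon between them, or one breakpoint is
intronic and the other outside that gene; an inversion spanning whole genes
with intergenic breakpoints is noncoding. DEL/DUP/MEI are coding iff any
coding base is affected. Rare mobile-element insertions are represented in
the data model (ALU/SVA/LINE1) but excluded from burden analysis, as their
calls are too noisy at standard coverage.

For burden counting, an SV qualifies in an annotation when it covers at
least 10% of at least one annotation element — the element length is the
denominator. The opposite reading (10% of the SV) exists in the wild; the
element-denominator reading is the default here and the alternative is a
one-line change in `element_overlap_fraction()` usage. Interval arithmetic
is 0-based half-open internally, with conversion to/from 1-based VCF
coordinates only at the I/O boundary; indexed overlap queries (IRanges) are
contract-tested against naive all-pairs scans.

## Burden model

For a target annotation the model is logistic regression of phenotype
(case = 1) on the per-sample qualifying-variant count:

* sequence-variant tests adjust for mean coverage, the phenotype-predicting
  principal components (each PC tested alone at two-sided p < 0.01,
  `select_covariates_phenotype()`), and the per-sample *total* URV count;
* SV tests adjust for the count-predicting PCs (multiple linear regression
  of the genome-wide ultra-rare SV count on sex, coverage and leading PCs,
  p < 0.05, `select_covariates_svcount()`) and include the genome-wide SV
  count as a covariate alongside the target-region count.

The odds ratio is per unit increase in burden; tests are one-sided for case
excess (upper-tail Wald). Empirical p-values come from phenotype-label
permutations (default 10,000): labels are swapped, covariates stay attached
to samples (this intentionally breaks any phenotype-covariate linkage under
the null, matching the label-swap description), the model is refit, and the
Wald z of the target term is compared with the observed one with an add-one
correction, `p = (1 + #[z_perm >= z_obs]) / (n_perm + 1)`, so p is never
zero. The z statistic (not the p-value) is permuted so non-convergent
refits can be counted conservatively as extreme; more than 1% of them
triggers a warning. Multiple testing uses Benjamini-Hochberg within
declared families — in the motivating design, 74 sequence-variant tests and
29 SV tests — with significance at adjusted p < 0.05. Family membership is
run metadata (`burden_scan(..., family = )`), since the exact family
composition is a configuration choice.

Separation is flagged at |beta| > 20; the permutation p remains computable
for flagged fits.

## Single-variant association and inflation

Common variants (MAF > 0.01) are tested by additive logistic regression
with two-sided Wald p-values. Without covariates the likelihood depends
only on the 3x2 genotype-by-phenotype table, so the scan vectorises Newton
iterations across variants on aggregated tables — identical estimates to
`glm`, orders of magnitude faster, which is what makes the 10^5-variant
null calibration run routine. Genomic inflation is
`lambda_GC = median(chi2_1) / 0.4549364`.

## Power

`cc_power()` follows the classic genetic power calculator parameterisation
for population-based case-control designs: additive penetrances
proportional to (1, g, 2g - 1) scaled so population risk equals the
prevalence K (1% lifetime risk by default); expected case/control
risk-allele frequencies by Bayes; and a two-sided normal test on those two
frequencies with *per-subject* sample sizes and unpooled variance. The
per-subject convention matters: an allele-count (2n) parameterisation gives
materially smaller minimal detectable risks and does not reproduce
published calculator output. `min_detectable_grr()` inverts the power
function by bisection (tolerance 1e-4) inside the penetrance-valid range
(the upper limit solves f2 = 1 in closed form). Aggregated burden power
treats the pooled URV carrier frequency as a single pseudo-variant (e.g.
aggregated MAF = 0.01). Monte-Carlo agreement of the analytic power with a
simulation oracle applying the same test is part of the test suite (within
0.02 across a MAF x risk grid).

## Heritability

GREML with the standard GRM (`compute_grm()`, mean-imputed residual
missingness) and, for GREML-LDMS, variants partitioned into 7 MAF bins with
boundaries 0.0007, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5 — the first bin is
(0.0007, 0.001] with 0.0007 itself included; the occasionally printed
descending form "0.0007-0.0001" is treated as a typo for this bin — each
split at its median windowed LD score (low strictly below the median, high
at or equal), giving up to 14 components. LD scores are windowed sums of
r^2 (10 Mb window, no r^2 cutoff, self included so scores are >= 1);
segment-based computation is an internal efficiency detail and the
windowed-sum definition is the tested contract.

`reml_fit()` estimates one variance component per GRM plus residual.
Single-GRM fits rotate into the GRM eigenbasis where the covariance is
diagonal, making Fisher-scoring iterations O(n) after one
eigendecomposition (reusable across phenotypes via `decomposition =`);
multi-GRM fits use average-information REML with an EM first step,
GCTA-style, with step-halving on likelihood decrease. Convergence is a
restricted log-likelihood change below 1e-8 (at most 100 iterations);
negative components are constrained to zero; standard errors come from the
(average) information matrix and the h2 standard error by the delta method.
Fixed-effect covariates (e.g. 10 PCs) enter the REML directly. For binary
phenotypes with a supplied prevalence K the observed-scale h2 is
transformed to the liability scale by
`K^2 (1-K)^2 / (z^2 P (1-P))`, z the standard-normal density at the
`qnorm(1-K)` threshold and P the sample case proportion.

## The synthetic-cohort generator

Individual-level data of this kind cannot be shared, so the package is
exercised end-to-end on synthetic cohorts (`sim_config()`,
`simulate_annotation_genome()`, `simulate_snv_cohort()`,
`simulate_sv_cohort()`, `simulate_liability_phenotype()`). Generator
defaults *are* the study conditions being emulated: 1162 cases / 936
controls; SNV/indel singleton fractions 45.43% / 37.03%; ~4250 URVs per
sample with an outlier tail (fraction 3%, rate multiplier 2); SV site
counts 17,895 DEL / 4,129 DUP / 4,458 INV with truncated-lognormal sizes
whose *truncated* medians equal 2592 / 7179 / 3265 bp on 500 bp - 1 Mb
(the location parameter is solved numerically; a naive
`meanlog = log(median)` misses the median by ~30% after truncation);
liability-threshold phenotypes at K = 1%. The toy genome (2 chromosomes of
25 Mb by default) is not a study condition and is freely scalable — tests
and examples use smaller genomes and thinner variant rates for speed, never
altered effect sizes.

Embedded burden effects are generated so that the estimand is exact: target
annotation URV counts are Poisson with case rate = OR x control rate, and
for Poisson class-conditional counts the prospective logistic regression
coefficient per unit count is exactly log(OR). Recovery bands used in the
acceptance tests were calibrated by Monte Carlo (200 seeds per effect size
at 500+500 samples, ~2000 target variants) before being frozen.
Singletons are heterozygous in exactly one sample by construction; all
randomness flows from one master seed through named substreams, so
identical configs give byte-identical cohorts.

What the generator does *not* emulate: read-level error, haplotype/LD
structure (beyond optional block correlation in the heritability
simulations), real ancestry gradients, and annotation co-occurrence
structure. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under its own assumptions, not robustness to
real-data artefacts.

## Problem sizes used by the test suite

The suite runs the full pipeline at reduced scale, chosen as the smallest
sizes at which the tested properties are statistically crisp: null
calibration of the one-sided burden test over 500 synthetic cohorts of
60+60 samples; permutation-p uniformity over 200 cohorts at 500
permutations each; a 10^5-variant null association scan at n = 600 for
lambda_GC; GREML recovery at n = 2000, m = 5000 over 20 seeds for h2 in
{0, 0.3, 0.5}; exhaustive oracle sweeps for the exact tests at small n.
The ascertained case-control GREML route (liability transform included) is
exercised at a reduced scale (3000-subject base population, K = 0.2,
300+300 ascertained) because a 1%-prevalence population oversampled to
thousands of cases would require simulating hundreds of thousands of
subjects per seed.

## Known limitations

* The permutation scheme does not permute covariates; when covariates are
  strongly phenotype-linked the permutation null is conservative for the
  covariate-adjusted statistic.
* The moment estimator of relatedness can stray slightly outside [0, 1];
  values are reported unclipped.
* AI-REML standard errors are asymptotic; with small n or components at the
  zero boundary they understate uncertainty.
* Fisher's exact p-values use probability-mass ordering; the doubling
  convention differs in the third decimal for some tables.
* chrX workflows (sex-stratified burden) are out of scope; all generators
  produce autosomes only.
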
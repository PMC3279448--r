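---
title: "Methods and design notes for betaclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for betaclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`betaclass` analyses the relationship between repetitive-element DNA
methylation (LINE-1 and AluYb8 bisulfite pyrosequencing, percent scale),
infant growth (birth weight percentile), and genomewide CpG methylation
measured as array β-values. This vignette records the statistical models,
the tunable parameters and their defaults, and the design decisions taken
where more than one reasonable implementation existed.

## The data model

Three linked tables drive every analysis:

* a **cohort** (one row per subject): sex, maternal age (years), BMI
  (kg/m²), ethnicity, tobacco/alcohol/prenatal-vitamin use, gestational
  age (days), birth weight percentile in (0, 100), and the two repeat
  markers on the 0–100 percent scale (LINE-1 summarised as the mean of 4
  assayed CpG positions, AluYb8 as the mean of 5);
* a **β-matrix** (loci × subjects) of methylation fractions
  β = max(M,0)/[max(M,0)+max(U,0)+100] computed from methylated (M) and
  unmethylated (U) intensities — the +100 offset keeps β strictly below 1
  and stabilises low-intensity loci; no normalisation is applied;
* a **locus annotation**: chromosome, CpG-island status, polycomb-target
  status, proximity (≤ 1 kb) to predicted transcription-factor binding
  sites with the factor identities, and mutually exclusive repeat-element
  overlap (Alu / LINE-1 / LINE-2 / MIR / none).

Percent and fraction scales are never mixed implicitly: pyrosequencing
values stay on 0–100, array β on 0–1, and regressions that report
"per 10%" effects divide the percent marker by 10 before fitting.

## Birth-weight regressions

Growth categories use strict cuts: SGA below the 10th percentile, LGA
above the 90th, AGA otherwise — so percentiles of exactly 10 or 90 are
AGA. Case–control matching is greedy and deterministic: cases in ID
order, eligible controls (same sex, ±3 years maternal age, ±2 days
gestation) ranked by age difference, then gestational-age difference,
then ID. A greedy scheme is not globally optimal, but it is reproducible
and transparent; unmatched cases are reported rather than fatal.

The adjusted model is ordinary least squares of birth weight percentile
on one marker (per-10% scale) plus infant sex (female referent), maternal
age, pre-pregnancy BMI, ethnicity (non-Caucasian referent), tobacco,
alcohol and vitamin use, on complete cases. Covariates that are constant
in a given cohort (in practice the rare-alcohol indicator in small
simulations) are dropped with a warning instead of producing an aliased
fit; genuinely collinear designs are an error naming the aliased terms.

## Recursively partitioned beta-mixture clustering

Loci are clustered with subjects as features. A mixture component models
locus *i*'s values as independent beta variates, one `(a_j, b_j)` pair
per subject *j*, so a component is a methylation *profile* across
subjects rather than a single distribution. Each tree node is tested for
a 2-way split by weighted EM:

* **E-step** — responsibilities from the product of per-subject beta
  densities, computed on log scale with log-sum-exp;
* **M-step** — exact weighted maximum likelihood for each component's
  per-subject shapes: the digamma system
  `ψ(a) − ψ(a+b) = E_w[log x]`, `ψ(b) − ψ(a+b) = E_w[log(1−x)]` solved by
  damped Newton iterations (vectorised over subjects), started from the
  method-of-moments estimate. Using the exact MLE rather than stopping at
  moments matters: it preserves EM's guarantee that the observed-data
  log-likelihood never decreases, which the test suite asserts on every
  EM trace. The extra Newton refinement costs little because it is a
  2-parameter solve vectorised across subjects.

Numerical choices: β is clipped to `[1e−4, 1 − 1e−4]` before likelihood
evaluation (beta densities diverge at the boundary); EM stops when the
relative log-likelihood change is below `1e−6` or after 500 iterations; a
component whose mixing weight falls below `1e−3` triggers a
single-component fallback and the split is abandoned. Initialisation is
deterministic — candidate loci are split at the weighted median of their
mean methylation — so a fit is exactly reproducible without a seed.

A split is accepted iff the 2-component BIC beats the single-component
BIC of the same loci, counting 2 shapes per subject per component plus
one mixing weight, with the node's effective membership as sample size.
Recursion stops after four splits, capping the tree at 16 terminal
classes. Loci are hard-assigned by maximum terminal responsibility
(fuzzy weights are used internally throughout the recursion), and classes
are renumbered by increasing mean methylation — class 1 lowest — with
mean ties broken by giving the larger class the lower index.

## Classing and the omnibus test

Bioinformatic classes are the observed tuples of the seven binary
attributes in the fixed order (CGI, PcG, TFBS, Alu, LINE-1, LINE-2, MIR);
only nonempty tuples enter the census, so the class count is data-driven
rather than fixed. Repeat flags are stored as four independent booleans
even though the generator draws them mutually exclusively — real
annotations can contain nested repeats. Aggregate class methylation is
the unweighted per-subject mean β over member loci; the size-weighted
mean of the aggregates therefore reconstructs each subject's global mean
exactly, which is tested.

The omnibus statistic is the maximum over classes of the absolute
t-statistic from the simple regression of each class aggregate on the
marker. Because a simple-regression t is a monotone function of the
correlation, the implementation computes the statistic (and its
permutation null) from correlation matrices, which makes the 10,000
permutations of a full-size analysis cheap. One shared marker shuffle is
used per permutation replicate across all classes — required, since the
maximum is over jointly permuted fits. The p-value uses the add-one
estimator `(1 + #{null ≥ observed})/(B + 1)`, which can never return 0;
the 0.95 null quantile is reported as a symmetric per-class limit, giving
family-wise multiplicity control for the per-class flags and the dashed
lines in `autoplot()`. Class regressions are unadjusted (marker only);
the rare perfect-fit case is capped at |t| = 1e8, and constant aggregates
yield t = 0 with a warning.

## GSEA

Loci are ranked by their simple-regression t against the marker (ties
broken by locus ID for stability). A set's enrichment score is the signed
maximum deviation of the weighted Kolmogorov–Smirnov running sum:
member loci add `|t|^p` normalised by the member total, non-members
subtract `1/(N − m)`; the default weight exponent is `p = 1`. The null is
built by **phenotype permutation** — shuffling the marker across subjects
and recomputing all locus statistics — which preserves the inter-locus
correlation structure that set-label permutation would destroy. NES
divides ES by the mean |null ES| of the same sign for that set; p-values
are add-one same-sign tail counts, and FDR q is the permutation NES-based
estimate (pooled same-sign null fraction over observed fraction, capped
at 1). Sets are filtered to between 5 and 500 members.

## The synthetic-data generator

Because the motivating study's cohort data were never deposited, the
package ships a generator whose defaults are calibrated once to the
study-level descriptive statistics, and validation proceeds by
parameter-recovery on synthetic cohorts rather than by re-fitting real
data.

* **Markers**: truncated bivariate normal on the percent scale, means
  51.7 / 65.0, SDs 4.6 / 3.3, correlation 0.29. At these parameters the
  [0, 100] truncation is essentially never active, so the configured
  moments are reproduced to within sampling error.
* **Covariates**: independent Bernoulli draws at prevalences 190/380
  (male), 217/380 (Caucasian), 36/380 (tobacco), 3/380 (alcohol), 314/380
  (vitamins); maternal age ~ N(29, 5²) truncated to [18, 40] years, BMI ~
  N(26.5, 5.5²) on [16, 45], gestational age ~ N(276, 8²) days on
  [260, 294] (term births). The continuous-covariate distributions are
  the package's own choices of plausible obstetric ranges; only the
  prevalences are calibrated.
* **Outcome**: percentile = 50 + structural marker effects + 12.81·(male)
  + 7.06·(Caucasian) (+ an optional tobacco effect, default 0) on centred
  covariates, plus N(0, 22²) noise, truncated to (0.1, 99.9). The
  configured per-10% marker effects (9.7 LINE-1, 14.5 AluYb8) are treated
  as **marginal** targets: since the markers are correlated, using them
  directly as joint-model coefficients would inflate every single-marker
  fit by omitted-variable bias, so the generator solves the 2×2 system
  relating structural to marginal coefficients and uses the structural
  solution. Fitted single-marker adjusted models then recover 9.7 and
  14.5 in expectation (`effects_are_marginal = FALSE` restores the naive
  behaviour). The residual SD of 22 percentile points is not a published
  quantity; it was chosen once so that coefficient standard errors are on
  the scale of the published interval half-widths while keeping outcome
  truncation rare (< 2% per tail). Truncation still attenuates the
  recovered coefficients by a few percent — visible in the validation
  experiments and accepted as a property of a bounded outcome.
* **β-matrix**: each locus joins one of 16 latent classes (equal mixing
  proportions) and draws per-subject values from Beta(μs, (1−μ)s) with
  class means on the fixed ladder 0.02 … 0.62 and precision s = 100. The
  ladder was chosen once so the matrix-wide mean (≈ 0.24) matches the
  genomewide scale of 27K-style arrays, neighbouring classes are
  separated by ≥ 0.02 (about 6 SEs of a locus mean at 100 subjects), and
  equal proportions keep the median-split initialisation aligned with the
  class hierarchy at every tree depth.
* **Annotation**: attribute frequencies CGI 0.73, PcG 0.12, TFBS 0.50,
  repeats Alu 0.08 / LINE-1 0.05 / LINE-2 0.04 / MIR 0.03, optionally
  class-dependent (e.g. enriching CGI in a chosen class); 258 TFBS
  identities with a long-tailed popularity profile so set sizes vary.

What the generator deliberately does **not** emulate: probe-level
intensities and batch effects, bisulfite conversion error, linkage
between a locus's methylation class and its annotation (unless
configured), dependence among binary covariates, and any spatial genomic
structure. Passing recovery tests on this synthetic world therefore
demonstrates the correctness and calibration of the *methods*, not the
reproduction of any real cohort's coefficients.

## Problem sizes and validation experiments

The default desk-scale β-matrix is 2,000 loci (the full-array analysis
used 26,486 autosomal loci after removing 1,092 X/Y loci from 27,578;
`n_loci` scales up by configuration). The validation suite runs: marker
correlation and effect recovery over 50 cohorts of n = 380; depth-4 RPMM
recovery on 2,000 × 100 with adjusted-Rand agreement against truth
(cross-checked with `mclust`); omnibus type-I error over 500 null
replicates at B = 200 (scaled down from the 10,000 permutations a
production analysis would use — B affects only p-value resolution, not
the observed statistic); a GSEA enrichment-score oracle on a worked
10-locus example plus an `fgsea` cross-check; and the exact-count
autosomal filter fixture. `scripts/acceptance.R` recomputes the headline
quantities from scratch under a caller-supplied seed.

## Known limitations

* The beta mixture assumes independence across subjects within a
  component; correlated subject effects (e.g. batch) would be absorbed
  into the shape parameters.
* The Mahalanobis screen operates on a 3-dimensional per-subject summary
  (mean β, SD β, fraction β > 0.7) with a χ²₃ threshold at α = 0.001;
  the summary choice is a package decision, and `alpha = 1` is read as
  "screen disabled".
* BIC split acceptance with 2 shapes × subjects parameters per component
  is conservative when loci are few relative to subjects; very small
  nodes (< 4 loci) are never split.
* The permutation FDR for GSEA can be noisy at small B; the add-one
  p-values are the primary inferential output.
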
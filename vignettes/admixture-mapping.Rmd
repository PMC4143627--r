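---
title: "Admixture mapping with admixscan: models, simulator and design choices"
author: "admixscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping with admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

# Scope

`admixscan` analyzes (and simulates) cohorts from a recently admixed
population — the reference setting is a three-way European (EUR) /
African (AFR) / Native-American (NAM) mixture with mean proportions near
0.6/0.1/0.3 and roughly ten generations of admixture on a single
chromosome spanning 2.217 morgans. This vignette records the models the
package fits, what the simulator does and does not emulate, and the
numerical and design decisions a careful reader will want stated rather
than implied.

# The two regression scans

Both scans operate on a residual trait: raw systolic or diastolic blood
pressure is log-transformed and residualized on intercept + age + sex by
ordinary least squares (`residualizeTrait()`), so `y` has mean zero.
Binary hypertension status can be analyzed with the same linear models on
the 0/1 indicator; this linear-model route is the reference path (a
logistic trait generator exists in the simulator, but the scans are
linear by construction).

**Ancestry-deviation (admixture-mapping) scan.** For the chosen ancestry
(European by default), `S_ij` is the local dosage in {0, 0.5, 1} and
`S̄_i` its unweighted mean across all scanned SNPs — no map-distance
weighting, since none is defined for the reference analysis. Per SNP,

$$y_i = \beta_0 + \beta_1 \bar S_i + \beta_2 (S_{ij} - \bar S_i) + \varepsilon_i$$

is fitted by OLS and $\beta_2 = 0$ tested with a t statistic on $n-3$
degrees of freedom. Splitting local ancestry into its individual-level
mean and the local deviation separates population stratification (carried
by $\bar S_i$) from the local mapping signal (carried by the deviation).
The implementation residualizes both `y` and the deviation regressor on
$[1, \bar S]$ (Frisch–Waugh), which is algebraically identical to the
three-column fit and vectorizes across SNPs; tests verify agreement with
brute-force normal equations to 1e-8.

**Ancestry-adjusted genotype scan.** With `G_ij` half the nonreference
allele count, `α_ijk` the local dosage of ancestry `k`, and `q_jk` the
ancestral nonreference allele frequency,

$$y_i = \beta G_{ij} + \sum_{k=1}^{K} \beta_k\, \alpha_{ijk}\, q_{jk} + \varepsilon_i$$

is fitted per SNP and $\beta = 0$ tested on $n-(K+1)$ degrees of freedom.
The rationale: $E[G_{ij} \mid \alpha_{ij\cdot}] = \sum_k \alpha_{ijk} q_{jk}$,
so the adjustment terms absorb exactly the ancestry-predictable part of
the genotype, and only the within-ancestry allelic signal is attributed
to $\beta$. The model is fitted **without an intercept**, exactly as
written; note that whenever the $q_{jk}$ are nonzero the $K$ ancestry
regressors span a constant column anyway (because $\sum_k \alpha_{ijk} = 1$),
so the intercept is implicit. A config flag adds an explicit intercept;
if that makes the design rank-deficient the aliased column is dropped and
the fit is unchanged. A SNP is *flagged* (p = 1, no estimate) only when
`G` itself lies in the span of the adjustment columns — then $\beta$ is
unidentifiable; redundancy purely among adjustment columns is resolved by
dropping aliased columns, with the degrees of freedom reduced accordingly.

**Multiple testing and calibration.** p-values are BH-adjusted
(`bhFdr()`, delegating to `stats::p.adjust`) with the discovery
threshold q < 0.05. Genomic control converts each two-sided p to a 1-df
chi-square quantile and divides the median by 0.4549; computing λ from
p-values rather than squared t statistics keeps the small-sample t
reference correct. λ is attached per scan but deserves a caveat: the
ancestry-deviation statistic varies along the chromosome only at tract
resolution (about `4a(1−a)gL ≈ 21` diploid segments per individual at
g = 10), so a single-chromosome scan contains only dozens of effectively
independent loci and its realized λ fluctuates by ±0.1 or more around 1
even for a perfectly calibrated test. The package's calibration tests
therefore check λ of the deviation scan on ancestries drawn independently
per SNP, and λ of the genotype scan (whose per-SNP Bernoulli noise *is*
independent) on full tract-structured cohorts.

**Permutation excess-signal test.** `permutationExcessTest()` counts SNPs
with |t| above a threshold (default t* = 3; a signed `t > t*` mode is
available since the verbal description "greater than 3" is ambiguous
about sign), permutes the residualized trait uniformly B times (default
3000), recounts, and reports the add-one estimator
$p = (1 + \#\{b: c_b \ge c_{obs}\})/(B+1)$, which can never be zero. The
residualization is computed once and the *residuals* are permuted; age
and sex are exchangeable with the trait under the null of no
genotype/ancestry effect, and permuting residuals keeps the scan closure
cheap.

# The simulator

`simulateCohort()` emulates the statistical structure the scans assume,
with ground truth exposed for every latent quantity:

* **Global proportions**: Dirichlet(concentration × meanProps) per
  individual. Defaults: meanProps = (0.6, 0.1, 0.3), concentration = 30,
  giving an SD of the European proportion of about 0.09 — a plausible
  spread for a single admixed cohort while keeping the admixture
  proportion well away from 0/1 for every individual.
* **Tracts**: along the genetic map, ancestry switch points form a
  Poisson process of rate g per morgan per haplotype; the ancestry after
  each switch is redrawn independently from the individual's own global
  proportions, and self-switches are collapsed. This yields the two-class
  switch rate 2a(1−a)g per morgan per haplotype — exactly the 4a(1−a)gL
  expected diploid switch count that the generations estimator inverts —
  and exponential tract lengths. Defaults: g = 10 on a 2.217-morgan map.
* **Allele frequencies**: per SNP, a shared ancestral frequency uniform
  on [0.1, 0.9] (avoiding near-fixed sites), then one Balding–Nichols
  draw per population with per-population drift (default 0.15 each).
  Under this model the *pairwise* Nei Fst between two populations with
  drift F each concentrates near F/2·(1+o(1)), about 0.07–0.08 at the
  defaults — similar in magnitude to continental human pairs.
* **Genotypes**: given the haplotype's local ancestry at a SNP, the
  allele is Bernoulli(q of that ancestry); sites are independent given
  ancestry (no background LD within ancestral populations).
* **Traits**: log(SBP) and log(DBP) are Gaussian around linear predictors
  with age (years, uniform 30–70), sex (Bernoulli 0.5), optional ancestry
  and genotype effects and residual SD 0.1 on the log scale (defaults:
  intercepts log 120 / log 75 mmHg, age effect 0.004/yr, sex effect
  0.03). Hypertension is, by default, a liability threshold: an SBP-scale
  liability with its own noise draw, thresholded at the empirical
  quantile that yields a 33% prevalence. Since the reference analysis
  does not state how case status was modeled, a logistic link is also
  available, but the threshold mechanism is the default because it
  reproduces the target prevalence exactly in-sample.
* **Seeds**: one master seed; global proportions, covariates, each
  individual's haplotypes/alleles, and traits use fixed substreams, so
  identical seeds give bit-identical cohorts.

`perturbAncestry()` corrupts a hard-called call set: with probability
`flipRate` per (SNP, individual), one of the two haploid labels is
replaced by a different uniformly chosen label. Because replacing one
haploid label with a different one always changes the unordered diploid
pair, the expected diploid inconsistency against the truth equals the
flip rate — convenient for emulating, e.g., an 18% disagreement between
two inference methods.

**What the simulator does not emulate**: coalescent genealogies,
background LD within ancestral populations, family structure, sex
chromosomes, genotyping error, or phase uncertainty. Consequently,
passing tests demonstrate correctness of the statistical machinery under
the assumed tract/frequency model — not robustness to LD-induced
miscalibration or to local-ancestry inference error beyond the simple
flip model.

# Segment counts and the generations estimator

`countSegments()` counts maximal runs of constant ancestry per haplotype
and sums the two haplotypes. For the estimator the labels are binarized
to European vs non-European, since the 4a(1−a) factor is a two-class
switch rate with a the European proportion. From dosage-only input the
diploid count is reconstructed as `2 + Σ_j |2d_{j+1} − 2d_j|` for a
target ancestry (each haploid switch moves the dosage by 0.5), or via
minimal multiset edits between adjacent unordered diploid states for
multi-way counting; both are invariant to SNP density as long as
adjacent SNPs flank every switch point, and undercount only when two
switches fall between adjacent SNPs.

`estimateGenerations()` computes `N = A/(4a(1−a)L)` literally. Every
diploid individual carries two baseline segments even with no
recombination, so the literal estimator is biased upward by
`2/(4a(1−a)L)` generations (≈ 0.94 at a = 0.6, L = 2.217). The bias is
left in deliberately — reproducing the published arithmetic is the point
— and the parameter-recovery tests document it by requiring the estimate
to fall in [g − 1, g + 2].

Both a pooled and a per-individual correlation with global ancestry are
computed by `compareToGlobal()` (labeled accordingly), since summary
tables in the literature rarely say which variant they report.

# AIM selection

`fstTwoPop()` implements the Nei-style estimator
`(H_T − H_S)/H_T` from population frequencies with equal weights — the
natural choice when only published frequencies, not sample sizes, are
available (no Weir–Cockerham weighting). `selectAims()` applies the
three conditions with strict inequalities exactly as stated (< 0.1 within
the Native-American pair; > 0.2 for all four cross-continent pairs;
LD r² < 0.1), then prunes greedily left-to-right in map order within a
250-SNP window — the pruning details are unspecified in the reference
description ("performed automatically"), so the simplest deterministic
scheme was chosen and the window exposed as a parameter. The condition
set (which pairs are "within" and "between") is configurable rather than
hard-coded, since requiring high CEU–YRI differentiation *between each
other* is a defensible variant the reference text leaves open. The
pipeline obtains the within-continent pair by splitting the simulated NAM
population into two lightly drifted subpanels (`splitPopulation()`,
drift 0.02), emulating closely related reference panels such as Maya and
Pima.

# Power module

For a dominant penetrance model, the carrier ("exposure") probability
under Hardy–Weinberg is `p0 = 1 − (1 − MAF)²` (9.75% at MAF 5%). A
genotype relative risk R maps to the case exposure by Bayes,
`p1 = R p0 / (R p0 + 1 − p0)`. Power uses the standard two-sided
pooled-SE normal approximation of the two-proportion z-test; this method
was chosen because it reproduces the published 80%-power/GRR-14.4 pair
from the published inputs (36 cases, 72 controls, α = 0.05/37,438), and a
two-sided test is assumed for the same reason. `grrForPower()` inverts by
bisection on [1, 1000] (power is monotone in the relative risk). At very
small case counts (n ≈ 36) the normal approximation sits ~0.02–0.03 away
from exact binomial simulation; agreement is within 0.02 by n = 100
cases, as the test suite verifies against a Monte-Carlo oracle.

# Numerical choices and degenerate inputs

* Genetic positions are stored in centimorgans in files and objects; all
  rate formulas convert to morgans. Physical positions are 1-based, as in
  VCF.
* Hard-calling fractional dosages snaps each K-vector to the nearest of
  the K(K+1)/2 valid diploid configurations in Euclidean distance, ties
  broken by population order (homozygous states first).
* A deviation regressor that is numerically constant (sum of squares
  < 1e-10 after residualization) flags the SNP with p = 1 rather than
  dividing by ~0; p-values are floored at the smallest positive double so
  they stay in (0, 1] even when a noiseless signal underflows.
* The missingness filter drops SNPs with *strictly more than* 20%
  missing genotypes at load time; multi-allelic VCF records are skipped
  with a logged count. Allele/strand harmonization of external panels is
  out of scope; loaders assume pre-harmonized alleles.
* TSV dialects write doubles with 17 significant digits so
  `read(write(x))` round-trips bit-exactly; every writer accepts comment
  lines and the pipeline records its seed in each output header.
* The pipeline validates its whole configuration (thresholds in range,
  known stage names, known trait columns) before creating any output.

# Problem sizes used by the test suite

The stochastic checks run at sizes chosen to give the assertions clear
Monte-Carlo margins while staying desk-scale: type-I error of both scans
from 200 null cohorts of 500 SNPs × 200 individuals (bands ±0.015 around
0.05); λ calibration at 10,000 SNPs; parameter recovery at n = 500 for
g ∈ {5, 10, 20}; confounding control from 20 cohorts simulated with
drift 0.5 and a pure ancestry effect (trait = global European proportion
+ N(0, 0.1)); permutation uniformity from 200 runs at B = 99 with
threshold t* = 2 — at t* = 2 the permutation counts are well spread
(expected ≈ 24 of 500 SNPs), so the add-one estimator's tie-induced
conservatism stays small, whereas at t* = 3 the counts are tiny integers
and the mean p would sit visibly above 0.5 for that discreteness reason
alone.

# Known limitations

* The scans are OLS-based; no mixed-model/kinship correction, no family
  data, no case-only admixture statistics.
* The simulator's independence of sites given ancestry means AIM LD
  pruning is exercised mostly by ancestry-induced correlation, not
  background haplotype LD.
* The generations estimator assumes a two-class (European vs other)
  switch process with a single map length; multi-chromosome aggregation
  is the caller's responsibility.
* `readGenotypes()` assigns genetic positions at 1 cM/Mb when reading a
  VCF without an accompanying map; supply a real map for analyses where
  the genetic scale matters.
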
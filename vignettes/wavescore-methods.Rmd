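---
title: "Wavelet-based multilocus score tests for rare variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based multilocus score tests for rare variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavescore)
```

## The problem

Single-SNP association scans have little power against traits driven by
*multiple rare* functional variants: each variant's marginal effect is too
small and its carrier count too low. Collapsing (burden) tests pool the
(weighted) genotypes of a region into one score, which recovers power when
most pooled variants are causal but buries the signal in noise when they are
not — pooling is the crudest possible smoother of the multilocus genotype
profile. `wavescore` implements a windowed association test that replaces
naive pooling with wavelet denoising: each individual's weighted multilocus
genotype vector is transformed to wavelet coefficients, the coefficients are
shrunk by empirical Bayes thresholding, the vector is inverted back, and a
multilocus score statistic is computed on the denoised profiles. Because the
thresholding happens per individual, an isolated rare variant carried by a
few individuals survives (it is a large, sparse coefficient), while diffuse
noise across the window is removed.

## The statistic

For a window of $m$ SNPs, let $X$ be the $n \times m$ matrix of weighted,
stratification-adjusted, denoised genotypes, with each column centred, and
let $Y$ be the length-$n$ residual trait (mean zero). The test uses the
score construction

$$U_j = \sum_i X_{ij} Y_i, \qquad
  V_j = \frac{\sum_i Y_i^2}{n-1} \sum_i X_{ij}^2, \qquad
  T = \frac{\sum_j U_j}{\sqrt{\sum_j V_j}},$$

i.e. per-SNP score components standardised by the square root of the summed
null variances. $V_j$ is the exact permutation variance of $U_j$ (over
random reassignment of $Y$), which makes $T$ scale-free; its null
distribution is nevertheless *not* assumed normal — inference is by
permutation of the residual trait, so the form of $V_j$ affects power, not
validity. Two-sided rejection on $|T|$ is the default.

Each preprocessing stage exists to remove a specific source of inflated
type-I error observed in practice:

1. **Minor-allele orientation and weighting.** Dosages count the minor
   allele; each column is divided by $\sqrt{n q (1-q)}$, with $q$ the
   estimated MAF, so rare alleles are up-weighted. Monomorphic SNPs are
   dropped (the weight is undefined at $q \in \{0,1\}$); missing genotypes
   are imputed to the rounded per-SNP mean, which preserves the integer
   dosage domain.
2. **Stratification adjustment.** With $C$ the $n \times k$ matrix of
   leading eigenvectors of the covariance of column-standardised dosages,
   every quantity entering the test — weighted genotypes, trait, covariates
   — is replaced by its projection residual $Z - CC'Z$. The number of
   components is chosen by an eigenvalue-gap heuristic
   (`select_num_components()`): the largest index whose eigenvalue exceeds
   its successor by a configurable factor (default 2) or stands out from
   the median of the remaining spectrum. A spectrum like
   23.1, 15.1, 3.0, 2.9, ... yields $k = 2$. The heuristic is deliberately
   greedy — removing a few extra components from a null genome costs almost
   nothing, while missing a structure axis inflates every test — and an
   explicit `pca_k` always overrides it.
3. **Residualization.** The tested trait is regressed (OLS with intercept)
   on its known influences — e.g. Q1 on Age and Smoking; the binary
   affection status on Q1, Q2, Q4, Smoking, and Age — and the residuals are
   tested. The binary trait goes through the same linear fit by default
   (a linear probability model): the residual construction only needs the
   fitted conditional mean removed, permutation inference does not rely on
   Gaussian errors, and the linear fit keeps the residuals exactly
   orthogonal to the predictors. Logistic residualization was considered
   and rejected as the default because the downstream permutation test
   would not gain validity from it, at the cost of a nonlinear dependence
   of the "residual" scale on the covariates.
4. **Windowing.** Fixed windows of 8 consecutive *nonsynonymous* SNPs per
   chromosome (non-overlapping; a trailing partial window is kept when it
   has at least 2 SNPs, since a 1-SNP "window" degenerates to a single-SNP
   test). Gene windows (all nonsynonymous SNPs of a gene, skipping genes
   with fewer than 2) are available but empirically carry higher type-I
   error as gene size grows; fixed size 8 is the default. Fixed windows do
   not cross chromosome boundaries but may cross gene boundaries within a
   chromosome.

## Wavelet denoising

The weighted multilocus genotype of one individual on one chromosome is a
piecewise-constant, sparse, noisy signal. It is zero-padded to the next
power of two and decomposed with an orthogonal periodic filter bank (Haar by
default — matched to piecewise-constant signals; Daubechies-4 available) to
the maximal depth the filter support allows. The padding/truncation boundary
rule was chosen over reflection or periodization of the raw signal because
it restores the original length exactly and keeps the operator orthogonal.

Detail coefficients are shrunk under a spike-and-slab prior
$u \sim (1-w)\,\delta_0 + w\,\mathrm{Laplace}(a)$ with Gaussian noise:

* the noise scale $\sigma$ is `median(|finest details|)/0.6745`, shared
  across levels (if the MAD is zero but details are not, the standard
  deviation of all details is used instead);
* the mixing weight $w$ is the marginal maximum-likelihood estimate from
  the coefficients of each resolution level separately (the
  *level-dependent* threshold; `level_dependent = FALSE` pools all levels).
  The marginal log-likelihood is concave in $w$, so the maximiser is found
  by bisection on its derivative;
* each coefficient is replaced by the posterior median of $u$ given $z$,
  which is exactly zero iff $|z| \le t(w)$; the threshold $t(w)$ is
  computed by bisection and is monotone nonincreasing in $w$;
* approximation coefficients are never shrunk — the coarse mean structure
  of the window is the burden-like component of the signal and removing it
  would discard exactly the information collapsing tests keep.

The slab scale defaults to $a = 0.5$ on the noise-standardised scale, the
conventional default of empirical Bayes wavelet thresholding; the Cauchy
slab is out of scope. The posterior median and marginal likelihood are
closed-form in `pnorm`/`qnorm` and are validated in the test suite against
brute-force quadrature oracles to $10^{-6}$.

## Permutation inference and multiple testing

Empirical p-values come from permuting the residual trait across
individuals (genotypes fixed, so the denoising is computed once); under
permutation the variance term of $T$ is invariant, and the permuted
statistic for every window reduces to one inner product — the full scan is
a single matrix product per permutation block. The default estimator is the
add-one rank $p = (1 + \#\{|T^\pi| \ge |T|\})/(M+1)$, a valid p-value that
is never exactly zero (the plain proportion-of-$M$ variant is available).
The default $M$ is 60{,}000, matching the resolution needed to Bonferroni-
correct thousands of windows at level 0.05.

Two family-wise corrections are provided:

* **Bonferroni:** $\min(1, p \times \#\text{windows})$ on each window's own
  empirical p-value;
* **max-statistic:** compare each window's $|T|$ to the permutation
  distribution of the genome-wide maximum.

The max-statistic route is only valid when all windows share a null
distribution. The package ships a self-contained simulation
(`simulate_permcmp()`) demonstrating the failure mode: 100 independent
statistics, a 100,000-draw null sample each (mimicking permutations), and
1,000 alternative replicates in which variable 1 is shifted by 3. When the
99 null variables receive heterogeneous null distributions
($a_i + b_i e$, $a_i \sim N(0,1)$, $b_i \sim U[0.5, 1.5]$, drawn once per
run — fixed "window-specific" nulls, which is what makes the maxima
comparison misbehave), the maxima method's power collapses to nearly zero
while the Bonferroni method's is essentially unchanged. The functional
variable keeps the standard-normal null in both scenarios: its alternative
is defined as $3 + e$, and giving it a randomly drawn null width would make
the reported power an artifact of a single draw of $b_1$ rather than a
property of the correction method. Rejection is two-sided on $|X|$; the
magnitudes of the expected powers (about 0.3 for an effect of 3 at
per-variable level $5 \times 10^{-4}$) are consistent only with two-sided
thresholds. "Type I error" here is the family-wise rate — the proportion of
replicates with at least one false rejection among the 99 null variables;
the per-test rate would be two orders of magnitude smaller than the
reported values.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of the benchmark this method was
developed for — about 700 unrelated individuals, genes of clustered rare
nonsynonymous variants, population substructure, covariate-driven traits —
without reproducing any restricted dataset. Defaults: 697 individuals, 100
genes of 8 SNPs, ancestral MAFs uniform on (0.004, 0.02) (rare but
polymorphic at this cohort size), two equal subpopulations with
Balding–Nichols differentiation at a configurable $F_{st}$, Age/Sex/Smoking
covariates with conventional effect sizes (0.02 per year of age, 0.3–0.4
per binary unit), causal effects of 0.5 trait SD per minor allele
(rare-variant effect sizes are typically several times larger than
common-variant ones), unit residual SD, and a logistic affection model on
the quantitative traits. Columns that come out monomorphic are redrawn so
every replicate has a complete, stable window map. What the generator does
*not* emulate: linkage disequilibrium within windows (genotypes are drawn
independently given subpopulation frequencies), site-frequency-spectrum
shape, sequencing error, and relatedness. Calibration results on these
cohorts therefore demonstrate the *statistical* validity of the pipeline
(permutation calibration, family-wise control, stratification removal),
not its behaviour under realistic LD — on real data the wavelet's use of
LD structure is precisely what distinguishes it from naive collapsing.

## Numerical choices and degenerate inputs

* Signals shorter than 2 cannot be transformed; windows need at least 2
  SNPs.
* All-zero detail vectors leave a signal untouched; $\sigma = 0$ with
  nonzero details triggers the SD fallback.
* $w = 0$ maps every coefficient to zero (threshold $+\infty$); $w = 1$ is
  pure-slab shrinkage (threshold 0).
* A trait that is constant (or perfectly explained by its predictors)
  yields $T = 0$ and $p = 1$.
* Collinear predictor sets are fit by pseudoinverse with a warning; the
  residual projection is unique regardless.
* Bisection tolerances: $10^{-8}$ for thresholds and the mixing weight,
  $10^{-6}$ guaranteed for the weight estimate.
* Permutations are drawn in blocks of 2,000 to bound memory at a few MB per
  scan; the draw sequence (hence every p-value) is fully determined by the
  seed.

## Problem sizes used in the shipped experiments

The validation experiments in the test suite are sized to make their
Monte-Carlo error small relative to the tolerances they assert: the
correction-comparison table runs the full specification (100 variables,
100,000 null draws, 1,000 replicates), averaged over a few independent
runs because the empirical threshold estimated from a single 100,000-draw
null sample carries a standard error of about 0.03 on the power scale;
family-wise calibration uses 200 replicates of a 400-individual, 100-gene
null cohort at $M = 2{,}999$; the power comparison uses 50 replicates of a
697-individual cohort whose first gene carries 10 causal variants at
$M = 9{,}999$; permutation-calibration uses 500 repeats at $M = 999$. These
sizes are the package's own trade-off between precision and a test suite
that runs in minutes.

## Known limitations

* The score statistic aggregates *signed* per-SNP scores; windows mixing
  protective and deleterious variants of equal strength can cancel, as in
  any burden-type test. The wavelet step mitigates but does not remove
  this.
* Fixed windows depend on SNP order, not genomic distance; a window can
  span a recombination hotspot.
* The identity-link residual route treats the binary trait linearly;
  strongly unbalanced case-control ratios may prefer the logistic option.
* Permutation inference assumes exchangeable individuals after adjustment —
  family structure is out of scope.
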
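---
title: "Variance decomposition in twin cohorts: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition in twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinvar)
```

## The classical twin design

`twinvar` analyses quantitative traits measured on monozygotic (MZ) and
dizygotic (DZ) twin pairs. The design rests on the standard biometrical
decomposition of a trait into latent sources: additive genetic effects (A),
dominance genetic effects (D), environment shared by co-twins (C) and
environment unique to each individual, including measurement error (E).
Co-twins' latent factors correlate according to their genetic relatedness:

| source | MZ | DZ |
|--------|----|----|
| A | 1 | 0.5 |
| D | 1 | 0.25 |
| C | 1 | 1 |
| E | 0 | 0 |

so the expected within-pair covariance is $a^2 + c^2 + d^2$ for MZ pairs and
$0.5\,a^2 + c^2 + 0.25\,d^2$ for same-sex DZ pairs
(`expected_pair_covariance()`). With twins reared together C and D cannot be
estimated simultaneously — both are identified only through the contrast
between MZ and DZ resemblance — so model specifications exclude C+D
combinations by construction.

Key assumptions inherited from the design: equal means and variances across
birth order and zygosity (testable against the saturated model), equal
shared environments for MZ and DZ pairs, random mating, and no
gene-environment interaction. Opposite-sex DZ pairs (DZos) additionally
carry a cross-sex additive-genetic correlation $r_g$; under a
sex-limitation model the additive cross-twin covariance in DZos pairs is
$0.5\, r_g\, a_m a_f$ with $r_g$ fixed at 1 by default or estimated.

## Estimation

Models (saturated, ACE, ADE, AE, E) are fitted by full maximum likelihood on
complete pairs: each pair contributes a bivariate-normal log density with a
group-specific mean vector and expected covariance (`neg2_loglik()`).
Parameters are raw path coefficients whose squares are the variance
components, so nonnegativity needs no bound constraints; a non-positive-
definite implied covariance simply receives an infinite objective value so
the optimizer rejects it. Optimization is quasi-Newton (BFGS) from three
deterministic starting points — equal split, A-heavy, E-heavy — so results
never depend on a random seed; the best solution is polished with a finer
finite-difference step and the gradient norm is recorded in the fit's
`convergence` field. Identical data in any row order give identical fits.

Likelihood-ratio tests compare nested fits (`compare_models()`), with the
nesting chain E < AE < ACE/ADE < saturated enforced. P-values for dropping
a variance component are reported against the plain chi-square reference,
matching conventional twin-modeling reports; because the null value lies on
the boundary of the parameter space, the 50:50 chi-square mixture p-value
(half the plain one for 1 df) is logged alongside as `p_mixture`. The
model-selection sequence (`selection_sequence()`) mirrors the usual
workflow: fit ACE and ADE, take the one with the lower $-2\ln L$ (an exact
tie goes to ACE, with a message), then test the AE restriction against it
and against the saturated reference. When the saturated model is
unavailable (fewer than 2 usable pairs in a group), its comparisons are
flagged `NA` rather than aborting, so tiny cohorts complete with flags.

Confidence intervals for standardized proportions are profile-likelihood
intervals (`profile_ci()`): the set of values whose profiled $-2\ln L$ lies
within $\chi^2_1(0.95)$ of the minimum, found by bisection to a tolerance of
$10^{-5}$ on the proportion scale and clipped to $[0,1]$; estimates pinned
at a boundary yield one-sided intervals with an explicit flag. The profiled
nuisance optimizations are warm-started from the previous bisection step,
falling back to the full fit's parameters whenever the warm start scores
worse (a stale start from the opposite side of the minimum can otherwise
misconverge).

## Bivariate Cholesky decomposition

The association between two traits is decomposed with a bivariate AE
Cholesky model: lower-triangular path matrices $A$ and $E$ give
within-person covariance $AA' + EE'$ and cross-twin covariance $k\,AA'$
($k = 1$ MZ, $0.5$ DZ). The AE-only structure follows the univariate
conclusion that shared-environment and dominance terms are dispensable for
these traits. Derived quantities: heritabilities $h_i^2$, the genetic
correlation $r_A$, the unique-environment correlation $r_E$, the
model-implied trait correlation
$r = r_A\sqrt{h_1^2 h_2^2} + r_E\sqrt{e_1^2 e_2^2}$ (an identity the fit
reproduces at $10^{-8}$), and the fractions of $r$ attributable to A and E.
Those fractions sum to 1 but are deliberately not clamped to $[0,1]$: with
opposite-signed $r_A$ and $r_E$ a fraction can legitimately exceed 1.
$r_A^2$ is the share of one trait's genetic variance overlapping the
other's (`shared_variance_fraction()`).

The sign indeterminacy of a Cholesky factor is fixed by reporting
$a_{11}, e_{11} \ge 0$ (and nonnegative diagonals). CIs for $r_A$ and $r_E$
are profiled directly on the correlation by reparameterizing the second
trait's paths as $(\rho, s)$ with $a_{21} = \rho s$,
$a_{22} = \sqrt{1-\rho^2}\, s$. The phenotypic $r$ is given a Fisher-z
interval with $n$ = individuals, the standard choice for a correlation of
this kind; it slightly ignores the pair clustering and should be read as a
descriptive interval.

## The cohort simulator

`simulate_cohort()` is a first-class module, not a test fixture: it draws
the latent factors directly from the cross-twin correlation table above
(one shared A factor for MZ, two A factors correlated 0.5 for DZ —
$0.5 r_g$ for DZos — one shared C, D analogously with 0.25, independent E),
so the implied moments are exact by construction rather than calibrated.
Traits are simulated on a standardized latent scale and mapped affinely to
the configured mean and SD per sex, keeping scale and structure separate.
Singletons are generated as pairs with one member deleted, so
`complete_pairs()` performs real work. The default configuration
(`default_config()`) mirrors the study design the package targets: 254 MZ,
176 same-sex DZ and 156 opposite-sex DZ complete pairs plus 121 singleton
twins; a sense-of-coherence-like trait (men mean 64.1, SD 10.0,
$a^2 = 0.30$; women 61.7, 10.63, $a^2 = 0.51$) and a depressive-symptoms
trait (13.6/4.10, $a^2=0.37$; 15.3/4.94, $a^2=0.63$) with genetic
correlation $-0.82$ (men) / $-0.84$ (women) and unique-environment
correlation $-0.46$ / $-0.43$. The cross-sex genetic correlation defaults
to $r_g = 1$ — no sex-specific genetic factors — since no estimate of it is
reported for these traits.

Polygenic scores are simulated at the score level (`attach_pgs()`), not
from genotypes: the score is a weighted sum of the trait's own additive
factor and an independent *genetic* factor with the same twin correlation
structure, weighted so the population $R^2$ with the trait equals the
target. Both components being genetic makes MZ co-twins' scores exactly
equal and DZ co-twins' correlate 0.5, and caps the achievable $R^2$ at the
trait's heritability — requesting more raises an error, since a genetic
score cannot explain more than the additive-genetic share.

What the simulator does *not* emulate: non-normal phenotypes, scale floors/
ceilings of questionnaire sum scores, assortative mating, sibling
interaction, age effects, missingness mechanisms beyond removing whole
members, or genotype-level structure (no SNPs, no LD). Passing tests
therefore certify the estimators under the model's own assumptions, not
robustness to their violation in real questionnaire data.

## Descriptives and polygenic-score inference

Descriptive tables use the sample SD ($n-1$); sex differences are tested by
regressing the trait on a sex indicator with standard errors clustered on
twin pairs. Sex adjustment of trait correlations is within-sex mean
centering, equivalent to partialling out a binary sex covariate; age is not
adjusted for, matching the design's cross-sectional narrow age band.
Cronbach's alpha implements its defining variance-ratio formula and is not
clamped — negative values flag miskeyed or heterogeneous items.

Polygenic-score regressions standardize the score within the analysis
stratum (so a sex-stratified beta is per 1 SD of that stratum's score
distribution) and report the trait in raw units per score SD; fully
standardized coefficients are an option. The slope's variance uses the
cluster-sandwich estimator with the conventional small-sample factor
$\frac{G}{G-1}\frac{N-1}{N-k}$ and a $t_{G-1}$ reference ($G$ = pairs),
the convention of the major econometric implementations; with singleton
clusters this reduces exactly to the HC1 heteroskedasticity-robust
estimator. $R^2$ is the squared trait-score correlation per score, not
incremental over covariates. The sex-interaction test is a cluster-robust
Wald test of the sex-by-score coefficient in the pooled model.

The Bonferroni threshold is a report-layer parameter (`alpha / k`, 4
decimals in tables), not hard-coded to any particular test count.

## Numerical choices

* Convergence: BFGS with relative tolerance $10^{-12}$, two rounds (the
  second with finite-difference step $10^{-6}$); convergence is declared
  when the numeric gradient norm is small and the three starts agree.
* Non-PD covariances: objective value $10^{12}$ (finite, so numeric
  gradients stay representable), never an exception inside the optimizer.
* Profile bisection tolerances: $10^{-5}$ (proportions), $10^{-4}$
  (correlations).
* Ties and reflections: ACE preferred on exact ACE/ADE ties; Cholesky signs
  fixed by nonnegative leading paths.
* Degenerate inputs: all-missing traits, constant scores, single-sex
  interaction tests and single-cluster sandwiches raise informative errors;
  zero phenotypic correlation leaves explained fractions undefined (`NA`)
  with a warning.

## Problem sizes used in the test suite

The statistical test suite simulates at sizes chosen to make Monte-Carlo
error small relative to the asserted bands while keeping a default run
practical: recovery bias uses 200 replicates per heritability level at the
default design's group sizes; profile-CI coverage uses 500 replicates of
1000 pairs; bivariate recovery uses 4000 pairs per zygosity group;
interaction-test size uses 500 null replicates of 2000 pairs. Smaller
property checks (selection-sequence retention, rA-interval coverage,
interaction power, pipeline smoke runs) use 8–60 replicates with
correspondingly wider assertion bands.

## Known limitations

* No FIML contribution of singleton twins in the shipped estimators;
  analyses use complete pairs (singletons are counted and reported).
* No trivariate or higher Cholesky, no independent/common-pathway models,
  no direction-of-causation modeling.
* The boundary-aware mixture p-value is logged, not used for the headline
  decisions, mirroring common reporting practice.
* The Fisher-z interval on `r` ignores pair clustering (see above).
* Bonferroni counts, trait lists and stratification choices are user
  responsibilities; the pipeline only reports what it was asked.
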
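---
title: "Methods: pedigree-based heritability of diurnal preference"
author: "chronoherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based heritability of diurnal preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoherit)
```

## The problem

Diurnal preference (chronotype) — the propensity toward morning or evening
activity — is commonly measured with the 19-item Horne–Östberg
Morningness–Eveningness Questionnaire (MEQ), whose total score runs from 16
(extreme evening preference) to 86 (extreme morning preference). In
family-based cohorts, the question of interest is how much of the variation
in this score is attributable to additive genetic effects: the narrow-sense
heritability

$$h^2 = \frac{\sigma^2_a}{\sigma^2_p}, \qquad
  \sigma^2_p = \sigma^2_a + \sigma^2_e,$$

estimated from the covariance of the phenotype among relatives.
`chronoherit` implements the full analysis chain for such a study:
questionnaire scoring, pedigree validation and relationship matrices, the
polygenic variance-components model with maximum-likelihood estimation,
the descriptive/effect-size layer, and a gene-dropping simulator that
generates cohorts with the same statistical structure, so that every step of
the chain can be validated without access to any particular study's raw
data.

## The variance-components model

For $n$ individuals with phenotype vector $y$, fixed covariates $X$, and
additive relationship matrix $K = 2\Phi$ (twice the kinship matrix), the
model is

$$y \sim \mathcal{N}\!\left(X\beta,\; \Omega\right), \qquad
  \Omega = 2\Phi\,\sigma^2_a + I\,\sigma^2_e
         = \sigma^2_p\left[h^2 K + (1-h^2)\,I\right].$$

The diagonal of $K$ is $1 + F_i$ (inbreeding coefficient $F_i$); entries
between members of different families are zero.

### Estimation

`fit_polygenic()` maximizes the multivariate-normal likelihood by profiling
over $h^2 \in [0,1]$:

1. **Spectral rotation.** $K$ is block-diagonal over the connected families,
   so it is eigendecomposed family-by-family, $K_b = U_b D_b U_b'$, and $y$
   and $X$ are rotated by $U'$. Under the rotation $\Omega$ becomes diagonal
   with weights $w_i = h^2 d_i + (1 - h^2)$, and each likelihood evaluation
   costs $O(np)$ instead of $O(n^3)$. For a cohort of ~110 families of ~8
   members this reduces one decomposition of an $825\times825$ matrix to
   ~110 decompositions of $8\times8$ blocks.
2. **Profiling.** At each candidate $h^2$, the generalized-least-squares
   $\hat\beta(h^2)$ and the closed-form
   $\hat\sigma^2_p(h^2) = \mathrm{RSS}_w/n$ (ML; $n-p$ under REML) are
   plugged in, leaving a one-dimensional profile log-likelihood.
3. **Bounded search.** The profile is maximized with `optimize()` on
   $[0,1]$ at tolerance $10^{-8}$ and the endpoints are checked explicitly,
   so boundary optima ($\hat h^2 = 0$ or $1$) are found exactly and flagged
   (`$boundary`), not treated as errors. The search is deterministic: fits
   are bit-for-bit reproducible given identical input order.

ML is the default and reference method; REML is available via
`method = "REML"`. With $K = I$ the two variance components appear in the
likelihood only through their sum, so $h^2$ is unidentifiable; this input is
rejected with an error rather than returning an arbitrary split.

### Uncertainty and testing

The standard error of $\hat h^2$ is the curvature estimate
$\widehat{\mathrm{se}} = (-\partial^2 \ell_p/\partial (h^2)^2)^{-1/2}$ from
a numerical second difference of the profile log-likelihood (step $10^{-4}$,
taken inward at boundary optima; `NA` when the curvature is not negative).

The null hypothesis $h^2 = 0$ lies on the boundary of the parameter space,
so the likelihood-ratio statistic is compared against the 50:50 mixture of a
point mass at zero and $\chi^2_1$ (`lrt_pvalue()`): $p = \tfrac12
P(\chi^2_1 \ge 2\Delta\ell)$, which equals 0.5 at $\Delta\ell = 0$. A Wald
test based on $\hat h^2/\widehat{\mathrm{se}}$ would give different (usually
larger) p-values near the boundary; only the mixture LRT is reported.

### Covariate models

`polygenic_suite()` fits the four conventional covariate sets — none;
sex + age; sex + age + age² + sex×age; sex + age + residence zone — each on
its own complete cases (so `n` may differ by model, as in published
heritability tables). Continuous covariates are centred and scaled
internally for conditioning; coefficients are reported on the original
scale. Because covariates explain phenotypic variance without touching the
family covariance, the unadjusted $h^2$ is systematically smaller than the
adjusted one whenever covariates matter: if covariates independent of the
pedigree explain variance $\sigma^2_{cov}$ on the scale
$\sigma^2_a + \sigma^2_e = 1$, then

$$h^2_{\mathrm{unadj}} = \frac{\sigma^2_a}{1 + \sigma^2_{cov}}.$$

`covariate_variance()` inverts this identity, and
`sim_config_calibrated()` uses it to build generators that hit a given
adjusted/unadjusted pair (defaults 0.48 / 0.21, implying
$\sigma^2_{cov} = 0.48/0.21 - 1 \approx 1.286$).

## Kinship

`kinship()` implements the recursive (tabular) algorithm in ancestors-first
order: $\phi_{ii} = \tfrac12(1 + \phi_{f_im_i})$ and $\phi_{ij} =
\tfrac12(\phi_{f_ij} + \phi_{m_ij})$, with terms involving missing parents
equal to zero (a single recorded parent therefore behaves exactly as if the
missing one were a unique unrelated founder). The result is dense — at the
cohort scales targeted here (~10³ individuals) dense storage and block-wise
eigendecomposition are the intended downstream path.

The test suite checks this algorithm against an independent Monte-Carlo
oracle that drops discrete founder alleles down fixture pedigrees and counts
identity by descent. One case worth noting: the offspring of *double first
cousins* (whose parents have $2\phi = 1/4$, i.e. $\phi = 1/8$) has
inbreeding coefficient $F = 1/8$ and relationship-matrix diagonal
$1 + F = 1.125$ — a value sometimes confused with the $1.0625$ of an
offspring of single first cousins. The gene-dropping oracle confirms 1.125.

## Questionnaire scoring

The MEQ instrument is data, not code: the packaged YAML fixture
(`inst/extdata/meq_horne_ostberg_1976.yaml`) encodes the 19 items, their
option point values (per-item minima summing to 16 and maxima to 86), and —
for the clock-time items — the midpoint of each time range in decimal hours.
Translated variants that preserve the scoring can be loaded from a file with
the same layout.

Scoring choices:

* **No imputation.** A missing or out-of-range answer is an error naming the
  item; single omissions are expected to be resolved at source (as done by
  telephone follow-up in field studies), never guessed.
* **Preferred times** (Questions 1 and 2) are the midpoints of the selected
  ranges in decimal hours. Bedtimes after midnight are offset past 24
  (01:30 → 25.5) so cohort means remain meaningful; `wrap = TRUE` folds them
  back to clock time.
* **Typology** bands are 16–30, 31–41, 42–58, 59–69, 70–86, inclusive; they
  partition the full range (checked exhaustively over all 71 totals).

## The synthetic cohort generator

`simulate_cohort()` emulates a family-based cohort of the kind the model is
designed for. What it reproduces, and what it deliberately does not:

**Pedigree shape.** Each of 112 families (default) starts from a founder
couple; each couple has Poisson(2) + 1 offspring; across 3 generations
20% of offspring found a couple with an unrelated incoming spouse. The
expected family size is then $2 + s + 0.2s + 0.2s^2 = 7.4$ with $s = 3$,
i.e. ~829 individuals — matching a cohort of ~825 in ~112 families with
first- through third-degree relatives. Real recruitment graphs (proband
ascertainment, spouses' relatives, missing links) are not modelled.

**Phenotype.** Gene dropping: founders draw additive values
$\mathcal{N}(0, \sigma^2_a)$; each non-founder receives the parental
midvalue plus segregation noise
$\mathcal{N}\!\big(0, \tfrac12\sigma^2_a(1 - (F_f + F_m)/2)\big)$ (founders
are non-inbred; the inbreeding adjustment matters only in consanguineous
fixtures). Environmental noise is i.i.d. $\mathcal{N}(0, \sigma^2_e)$. This
generates exactly the covariance $2\Phi\sigma^2_a + I\sigma^2_e$ the
estimator assumes — which is the point: parameter recovery isolates
estimator error from model error.

**Covariates.** Age is truncated-normal (46.4 ± 16.3 on [18, 89]), sex
comes from the pedigree (60.2% female among free draws), residence is
Bernoulli (96/825 rural) — all drawn independently per individual. Drawing
ages i.i.d. rather than by generation is a deliberate default: it makes the
variance-inflation identity above exact, so the calibrated recovery
experiments measure what they claim to. In real data age is confounded with
pedigree position; the model ignores that, and so does the default
generator. Shared-household effects, assortative mating and spouse-pair
environmental correlation are likewise not simulated (and not modelled).

**Scale.** The latent phenotype is affinely mapped to centre 63.5, SD 11.2
(the questionnaire scale), then — when `censor = TRUE` — rounded to integers
and clipped to [16, 86]. Heritability is invariant to the affine map, so
the defaults use demographically plausible effect sizes (+0.263
points/year of age, +1.8 points for men, +7.6 points for rural residence).
Censoring attenuates $\hat h^2$ slightly; the suite measures the
attenuation (paired censored/uncensored runs, same seeds) and asserts it
stays below 0.05 at the default variance scale. The ceiling also produces
the characteristic downward bend in the upper tail of the normal Q-Q plot
that bounded questionnaire scales show in morning-shifted populations
(`qq_coordinates()` exhibits it on censored output).

**Calibrated mode.** `sim_config_calibrated()` is the estimator-validation
configuration: unit variance scale, uncensored, residence effect zero, and
sex/age effects sized by the variance-inflation identity (96% of
$\sigma^2_{cov}$ on age, 4% on sex — the ratio implied by the
demographically motivated effects, where the age effect dominates). Fitting
sex+age-adjusted and unadjusted models on these cohorts recovers the
generating pair (0.48, 0.21) in expectation; the acceptance script does
exactly this over 100 seeded cohorts. It is worth stating plainly that
effect sizes *this* large are not demographically realistic — the
descriptive-layer effects (≈0.26 points/year, ≈1.8 points for sex) explain
far less variance than the adjusted/unadjusted heritability gap implies.
The calibrated generator reproduces the statistical conditions the
heritability pair defines, not a literal demographic mechanism; the default
generator, conversely, is demographically plausible but will not reproduce
a 0.48/0.21 gap.

## Descriptive layer

* `cohens_d()` defaults to the **unweighted-variance** standardizer
  $\sqrt{(s_a^2 + s_b^2)/2}$. With strongly unequal group sizes this
  differs visibly from the size-weighted pooled SD (0.73 vs 0.69 for the
  rural/municipal summaries used in the examples); both are exposed. The
  confidence interval inverts the noncentral-t distribution of the
  standardized difference (asymmetric, as published intervals for d
  typically are); a symmetric normal approximation is available.
* `ttest_from_summary()` works from (n, mean, sd) triples; pooled is the
  default, Welch available.
* `pool_groups()` reconstructs a total-sample mean and SD exactly from
  subgroup summaries (within + between sums of squares); it is associative
  to numerical precision and is the identity on a single group.
* `age_trend()` is ordinary least squares of score on age (≥3 records, ≥2
  distinct ages); under a null generator its slope p-values are uniform
  (checked by a Kolmogorov–Smirnov test over 500 replicates).
* `histogram_counts()` and `qq_coordinates()` produce the figure-level
  data (per-score counts by group; ordered values against
  $\Phi^{-1}((i-\tfrac12)/n)$).

## Numerical choices and degenerate inputs

* Profile-likelihood tolerance $10^{-8}$; endpoint checks catch boundary
  optima that interior search would miss.
* Eigenvalues of $K$ clipped at zero after a PSD check with tolerance
  $-10^{-8}\max(1, \lambda_{\max})$; matrices failing it are rejected.
* SE step $10^{-4}$ on the $h^2$ scale; non-concave curvature yields `NA`
  rather than a fabricated SE.
* Rank-deficient designs, constant ages, zero SDs, out-of-range scores,
  pedigree cycles, sex-inconsistent parents and duplicate ids are all
  errors with the offending item/row named.
* The response allocator (`simulate_responses()`) is greedy over option
  steps with a swap fallback for parity; it reaches every total in 16–86
  (checked exhaustively).

## Problem sizes used in the validation suite

Parameter-recovery experiments use 100 replicate cohorts of 112 families
(~825 individuals each); kinship oracles use 20,000 allele drops per fixture
pedigree (≤12 members); likelihood oracles use a 30-individual fixture with
a 101-point grid; null-calibration checks use 500 replicates of n = 40.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances (e.g. the mean of 100 $\hat h^2$ values has SE ≈ 0.008
against a ±0.04 band) while keeping the full suite fast.

## Known limitations

* Only two variance components ($\sigma^2_a$, $\sigma^2_e$): no household,
  dominance, or marker-based components.
* The LRT mixture null is asymptotic; in very small pedigrees the boundary
  mixture weights deviate from 50:50.
* The curvature SE is a quadratic approximation; near boundaries the
  profile is asymmetric and a profile-likelihood interval would be more
  faithful.
* Passing recovery tests on generator output validates the estimator under
  its own assumptions; it says nothing about robustness to age–pedigree
  confounding, shared environment, or ascertainment, which real cohorts
  have and the generator deliberately omits.
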
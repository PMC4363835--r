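# chronoherit

Pedigree-based heritability analysis of diurnal preference (chronotype)
measured with the Horne–Östberg Morningness–Eveningness Questionnaire
(MEQ). The package is aimed at family-cohort studies in which the MEQ is
administered across multi-generation pedigrees and the question is how much
of the score's variation is additive-genetic.

It provides, end to end:

* **MEQ scoring** — the 19-item instrument as a versioned data fixture
  (total score 16–86), typology classification, preferred wake/bed times.
* **Pedigrees** — PED-file reading and validation, the additive
  relationship matrix `2Φ` by the recursive kinship algorithm,
  relative-degree classification.
* **The polygenic model** — maximum-likelihood estimation of
  `Ω = 2Φ σ²ₐ + I σ²ₑ`, reporting `h² = σ²ₐ/σ²ₚ` with a curvature-based
  standard error and a boundary-corrected (½χ²₀ + ½χ²₁) likelihood-ratio
  p-value, via a formula interface and the standard four covariate models
  (none; sex+age; sex+age+age²+sex×age; sex+age+residence).
* **Descriptives** — summary-statistic t-tests, Cohen's d with
  noncentral-t intervals, exact subgroup pooling, age trend, histogram and
  Q-Q figure data.
* **A synthetic cohort generator** — gene-dropping simulation of
  multi-family pedigrees and phenotypes with configurable variance
  components, covariate effects and scale censoring, so the whole chain is
  testable without any study's raw data.

## The model

For phenotype `y`, covariates `X`, and kinship-derived relationship matrix
`K = 2Φ`:

    y ~ N(Xβ, σ²ₚ [h² K + (1 − h²) I]),   h² = σ²ₐ / (σ²ₐ + σ²ₑ)

The likelihood is profiled over `h² ∈ [0, 1]` after a block-wise spectral
rotation of `K` (families are independent, so the eigenproblem decomposes),
with GLS fixed effects and closed-form `σ²ₚ` at each candidate `h²`. See
`vignettes/chronoherit-methods.Rmd` for the full account.

## Worked example

Simulate a small-town family cohort (112 families, ~800 adults,
morning-shifted scores with a rural/municipal contrast) and fit the
four-model heritability suite:

```r
library(chronoherit)

cfg <- sim_config(n_families = 112, seed = 42)
coh <- simulate_cohort(cfg)
coh
#> synthetic cohort: 769 individuals, 112 families, seed 42

polygenic_suite(coh$phenotypes, coh$pedigree)
#> Heritability by covariate model:
#>                      Covariates   N     h2 +- SE P-value
#>                            none 769 0.42 +- 0.07 1.1e-14
#>                       sex + age 769 0.47 +- 0.07 2.2e-16
#>  sex + age + I(age^2) + sex:age 769 0.47 +- 0.07 2.3e-16
#>           sex + age + residence 769 0.54 +- 0.07 2.3e-20
```

Each row is one covariate model: `N` its complete cases, `h2` the ML
estimate of the additive fraction of the covariate-adjusted phenotypic
variance, `SE` from the profile-likelihood curvature, and the p-value from
the boundary-mixture LRT of `h² = 0`. The generator's additive fraction is
0.48 of `σ²ₐ + σ²ₑ`; the sex+age-adjusted fit recovers it (0.47 ± 0.07),
the unadjusted fit is attenuated by the unmodelled covariate variance, and
adding age²/sex×age changes nothing, as those effects are absent from the
generator.

The descriptive layer works from raw vectors or published-style summaries:

```r
rural <- summarize_group(coh$phenotypes$meq_total[coh$phenotypes$residence == "rural"], "rural")
municipal <- summarize_group(coh$phenotypes$meq_total[coh$phenotypes$residence == "municipal"], "municipal")
rural
#> rural: n = 87, 71.37 +- 9.59
cohens_d(rural, municipal)
#> Cohen's d = 0.834 (95% CI 0.607, 1.061; unweighted_sd, noncentral_t)
tr <- age_trend(coh$phenotypes)
sprintf("%.3f points/year (p = %.2g)", tr$slope, tr$p)
#> "0.302 points/year (p = 2.9e-33)"
```

`run_pipeline()` (or `Rscript inst/cli/chronoherit.R run ...`) chains the
whole analysis and writes the report bundle: `table1.tsv`, `table2.tsv`,
`fig1_hist.tsv`, `fig3_age.tsv`, `fig4_qq.tsv` and `report.json`.

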
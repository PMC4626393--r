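# cohortbump

Automatic detection of **local birth-cohort effects** in age–period
tabulated mortality (or incidence) counts.

Age–period–cohort analysis is haunted by the exact identity
`cohort = period − age`: the three effects cannot be separated without
arbitrary constraints. `cohortbump` takes a different route. The observed
deaths in each (age, period) cell follow a Poisson model with a
varying coefficient on the log-rate scale,

    d_{a,p} ~ Poisson(z_{a,p} · λ_{a,p}),      log λ_{a,p} = β₀(a, p),

where `z_{a,p}` are person-years of exposure. The varying coefficient is a
tensor-product cubic polynomial surface in age and period — which absorbs
age effects, period effects, *and any gradual (global) cohort trend* —
plus a single Gaussian basis riding on the birth-cohort diagonal:

    β₀(a, p) = θ′x(a, p) + β_c · φ(p − a; μ_c, σ_c²),

with `x(a, p) = (1, a, a², a³, p, ap, …, a³p³)′` (16 terms) and `φ` the
normal density with mean `μ_c` (cohort center, a birth year) and standard
deviation `σ_c` (cohort width in years). For fixed `(μ_c, σ_c)` the
coefficients `(θ, β_c)` are estimated by Poisson maximum likelihood with a
log person-years offset; `(μ_c, σ_c)` themselves are chosen by minimizing
the profile deviance `−2ℓ(θ̂, β̂_c | μ_c, σ_c²)` over a grid of integer
years. The detected effect is reported as

* a Wald test of `β_c = 0` (z-value and two-sided p-value),
* the relative-risk curve `RR(c) = exp(β̂_c · φ(c; μ_c, σ_c²))` by birth
  year, whose extreme is `exp(β̂_c / (σ_c √(2π)))` at `c = μ_c`, and
* a local-vs-global classification: the bump is a *local* cohort effect
  only when `σ_c` is at most about 5% of the data's birth-year span; a wide
  optimum means the Gaussian term is merely helping the polynomials track a
  global trend, and no local effect is declared.

## Worked example

Simulate a registry-like table (17 five-year age groups × 11 five-year
periods, 10⁶ person-years per cell) with a positive bump planted on the
1950 cohort, then detect it:

```r
library(cohortbump)
tab <- simulate_table(default_scenario("bump-positive", seed = 7))
tab
#> Age-period table: 187 cells, 17 age group(s) x 11 period(s)
#>   ages 2.5-82.5 (width 5), periods 1962.5-2012.5 (width 5)
#>   total deaths 12819 over 1.87e+08 person-years
#>   birth cohorts 1880-2010 (span 130 years)

det <- detect_cohort_effect(tab, mu_grid = 1935:1965, sigma_grid = 1:8)
det
#> Birth-cohort effect detection
#>   best bump: center 1950, width 4 years
#>   beta_c = 4.6786 (SE 0.4728), z = 9.896, p <1e-16
#>   LOCAL cohort effect (width/span = 0.031, threshold rule)
#>   peak relative risk 1.595 at birth year 1950
#>   -2 log L: 1191.571 (bump) vs 1285.480 (null); drop 93.910
```

The grid search lands on the planted center (1950) and width (4 years);
`β̂_c = 4.68` (truth 4.3) is highly significant, the 4-year width is 3% of
the 130-year birth span (hence "LOCAL"), and cohorts born around 1950 have
a peak mortality rate 1.6 times the smooth age–period background.
`relative_risk_curve()`, `predict_surface()` and `write_fit_json()` export
the curve, the fitted Lexis surface and the coefficient table; real tables
are loaded with `read_age_period_table()` (long CSV/TSV, remappable column
names, "40-44"-style labels) or `read_age_period_matrix()` (wide layout).

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/cohortbump.R simulate --kind bump-positive --seed 7 --out sim.csv
Rscript inst/cli/cohortbump.R detect --input sim.csv --out results/ \
        --mu-grid 1935:1965 --sigma-grid 1:8
```

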
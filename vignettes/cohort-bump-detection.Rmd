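---
title: "Detecting local birth-cohort effects with a Gaussian-bump varying coefficient model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting local birth-cohort effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortbump)
```

## The model

Mortality tabulated by age group and calendar period carries three
confounded time scales: age, period, and birth cohort, linked by the exact
identity $c = p - a$. Classical age–period–cohort regressions need an
arbitrary identifying constraint, and different constraints give different
cohort stories. `cohortbump` instead asks a narrower, well-posed question:
*is there a short-lived departure from an otherwise smooth age–period
surface, concentrated on a few adjacent birth cohorts?*

For cell $(a, p)$ with person-years $z_{a,p}$ and deaths $d_{a,p}$,

$$d_{a,p} \sim \mathrm{Poisson}(z_{a,p}\,e^{\beta_0(a,p)}), \qquad
\beta_0(a,p) = \theta' x(a,p) + \beta_c\,\phi(p - a;\ \mu_c, \sigma_c^2),$$

where $x(a,p)$ collects all products $a^i p^j$, $i,j \le 3$ by default
(16 terms), and $\phi$ is the normal density in the birth year $p - a$.
The polynomial tensor surface absorbs age effects, period effects and any
*gradual* cohort trend (a smooth function of $p - a$ is locally a smooth
function of $a$ and $p$); the Gaussian term can only pay for itself, in
likelihood, by capturing something the polynomials cannot — a localized
ridge or trough along one diagonal of the Lexis surface. The cohort effect
is reported on the risk scale as $RR(c) = \exp(\beta_c \phi(c))$, with
extreme value $\exp\{\beta_c/(\sigma_c\sqrt{2\pi})\}$ at $c = \mu_c$.

Model assumptions worth keeping in mind: counts are pure Poisson (no
overdispersion parameter is estimated), cells are independent given the
surface, and each grouped cell is represented by a single point.

## Estimation

For fixed $(\mu_c, \sigma_c)$ the model is a Poisson GLM with canonical
log link and offset $\log z$, and $(\theta, \beta_c)$ are estimated by
iteratively reweighted least squares (`fit_ml()`, built on `stats::glm.fit`).
The start is deterministic — all coefficients zero except the intercept at
$\log(\sum d / \sum z)$ — and convergence requires a relative deviance
change below $10^{-10}$ (a maximum absolute score component below
$10^{-8}$ is also accepted), within 100 iterations by default. Standard
errors come from the inverse observed Fisher information
$X' \mathrm{diag}(\hat\mu) X$, which equals the expected information under
the canonical link. Inference on $\beta_c$ is a Wald z-test, matching the
way such coefficient tables are conventionally printed; the deviance drop
against the bump-free model is reported as a secondary index (see
Limitations).

The pair $(\mu_c, \sigma_c)$ is profiled out by grid search
(`grid_search()`): the model is refitted at every candidate pair and the
pair minimizing $-2\hat\ell$ wins. Default grids use integer years —
$\mu_c$ over the observed birth-year range trimmed by $\max(\sigma)$ at
each end, so an edge bump cannot be carried by a single corner cell, and
$\sigma_c \in 1, \ldots, \min(15, \mathrm{span}/4)$. Exact deviance ties
are broken toward the smallest $\sigma_c$, then the smallest $\mu_c$: the
most local, earliest explanation. A grid point whose fit fails or does not
converge is excluded (with a warning count) rather than aborting the
search.

## Local versus global

A wide optimum is informative: when no local change exists the Gaussian
term drifts toward fitting the residual global cohort trend jointly with
the polynomials, and the fitted $\sigma_c$ inflates. `classify_local()`
therefore declares a *local* effect only when
$\sigma_c / \mathrm{span} \le 0.05$, where span is the observed
$\max(p-a) - \min(p-a)$. Both the threshold (default 5%) and the span are
explicit arguments: "the whole range of birth year" could equally be read
as a fixed window, so the definition is exposed rather than hard-coded.
The boundary is inclusive — a ratio exactly at the threshold counts as
local — and the ratio is always reported so the rule can be revisited.

## Numerical and representational choices

* **Category midpoints.** Five-year groups are represented by interval
  midpoints ("40–44" → 42.5, treating the group as $[40, 45)$). Whether
  published analyses used midpoints or lower bounds is generally not
  stated; the convention is configurable (`label_convention`), and because
  $\phi$ is evaluated at real-valued $p - a$ the choice shifts $\mu_c$ by
  at most the offset between conventions.
* **Standardization.** Age and period are standardized to mean 0 / sd 1
  (constants computed from the table's cells and stored in the
  `basis_spec`) before powers are taken — cubic terms over ranges of
  decades are otherwise severely ill-conditioned. Consequently $\hat\theta$
  is only comparable between fits sharing a scaling, while $\beta_c$,
  $(\mu_c, \sigma_c)$ and all relative risks are scale-free: $\phi$ is
  always evaluated on raw $p - a$ in calendar years, so bump parameters
  read directly as birth years.
* **Likelihood constant.** The $-\log d!$ term is kept, making
  $-2\hat\ell$ an absolute quantity; it cancels in any within-table model
  comparison, which is the only use the grid search makes of it.
* **Guards.** Zero-exposure cells are dropped at load (they contribute
  nothing to the likelihood); a linear predictor beyond $|50|$ triggers a
  warning (likelihood evaluation) or a pre-sampling error (simulator),
  since such rates signal a mis-scaled scenario rather than data.

## What the simulator emulates — and what it does not

`default_scenario()` draws Poisson counts from the model itself on a
17 × 11 grid of 5-year age groups (midpoints 2.5–82.5) and periods
(1962.5–2012.5), constant exposure $10^6$ person-years per cell, and a
smooth cubic background with rates between roughly $3\times10^{-6}$ and
$3\times10^{-4}$ per person-year — rising in age, declining in period,
i.e. registry-like cancer-mortality magnitudes. The planted bump sits at
$(\mu_c, \sigma_c) = (1950, 4)$ with $\beta_c \in \{+4.3, -1.4, 0\}$,
echoing the strongly positive (liver-like), moderately negative
(lung-like) and null cases. $\theta$ is defined on the standardized scale
so a scenario is invariant to the grid's extent; all randomness flows from
one integer seed.

Real registry tables differ in ways the simulator deliberately ignores:
exposure varies by orders of magnitude across a population pyramid (a
per-cell exposure vector can be supplied), counts are often overdispersed,
rates contain non-polynomial structure, and real cohort effects need not
be Gaussian in shape. Passing tests therefore demonstrate correctness of
the estimation and detection machinery *under the model's own
assumptions* — parameter recovery, test size, coverage — not robustness to
misspecification.

Problem sizes in the test suite were chosen to characterize the sampling
properties tightly while staying desk-scale: 100 seeded replicates for
bump recovery over a 41 × 10 grid, 1000 replicates for the size of the
Wald test, 100 for interval coverage, 30 for the null distribution of the
grid-searched deviance drop, and 20 random small tables for equivalence
with an independent quasi-Newton maximizer of the same likelihood
(agreement required to $10^{-6}$ in $-2\hat\ell$).

## Limitations

* **One bump.** A single Gaussian basis is searched; data with several
  local cohort effects (a plausible reading of some lung-cancer series,
  where a second late-1920s candidate is visible) will surface only the
  dominant one. Inspecting `grid_search()$grid` for secondary minima is a
  pragmatic workaround, but a principled multi-bump extension is future
  work.
* **Search-unadjusted inference.** The Wald p-value for $\beta_c$ is
  computed at the grid optimum and inherits the optimism of any
  post-selection test; likewise the deviance drop is the extreme over the
  grid, not a $\chi^2_1$ draw. The null-calibration test quantifies this
  on simulated data; treat borderline p-values with corresponding caution.
* **Pure Poisson.** No quasi-Poisson or negative-binomial option;
  overdispersed data will yield anti-conservative tests.
* **Grouped data.** One representative point per cell; very wide
  categories blur bumps narrower than the category width, so $\sigma_c$
  below the age-group width should be read as "at most one group wide"
  rather than as a precise width.
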
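---
title: "Methods: constructing a child social exclusion index and relating it to child health outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing a child social exclusion index and relating it to child health outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csehealth)
```

## The problem

Children's risk of social exclusion varies strongly between small areas, and
so do their health outcomes. This package implements a small-area analysis
with two halves:

1. **Index construction.** Thirteen census-style indicators of child social
   exclusion, grouped into five domains (socio-economic background, education,
   connectedness, housing, health service access), are combined into a single
   composite score per area, and areas are cut into child-population weighted
   quintiles of risk.
2. **Outcome association.** Area-level rates of potentially preventable
   hospitalisations (PPH: admissions avoidable with adequate primary care) and
   quintile-level avoidable-death rates are related to the index through
   weighted correlations, quintile concordance cross-tabulations, gradient
   tests, polynomial regression residuals analysed by remoteness, and
   contingency chi-square tests.

Because the unit-record hospital and mortality data behind such analyses are
restricted, the package ships a synthetic small-area generator with a known
latent disadvantage factor, so every stage can be tested end to end against
ground truth, plus two published quintile-level national tables (under
`inst/extdata/`) against which the concordance and contingency machinery is
validated.

## Index construction

### Filtering and orientation

Areas with fewer than 30 resident children aged 0–15, or with a census
non-response fraction of 0.80 or more on any indicator, are excluded
(`filter_areas()`; the population rule is strict "fewer than", the response
rule is inclusive). Eleven indicators are proportions where larger already
means higher risk; the three access ratios (GPs and dentists per 1,000
population, and an area-to-national ratio of Year 5 literacy/numeracy scores)
are negated so that larger always means higher risk (`orient_indicators()`).
Negation rather than reciprocal inversion is used because every downstream
step is either rank-based or applied to standardised values, for which any
order-reversing affine map is equivalent; negation is the one that is exactly
affine.

### Domain scores

Four domains are summarised by the first principal component of their
indicators (`score_domain_pca()`). Indicators are standardised to mean 0,
variance 1 over the included areas first — a correlation-matrix PCA — because
the indicators are on incomparable scales and deprivation indices of this
family conventionally weight indicators by correlation structure, not by raw
variance. This also makes domain scores invariant to rescaling any single
indicator by a positive constant (a property the test suite checks). Areas
enter the PCA unweighted; population weighting is applied only where the
analysis states it (quintile construction and correlations).

The sign of a principal component is arbitrary, so it is pinned
deterministically: the score must correlate positively with the unweighted
mean of the domain's standardised oriented indicators, guaranteeing "higher
score = higher risk" on every dataset. The Housing domain contains only two,
weakly correlated proportions; its score is their arithmetic mean
(`score_domain_mean()`).

### The exponential rank transformation

Domain scores are on arbitrary, mutually incomparable scales. Each domain is
therefore reduced to ranks and transformed (`exponential_rank_transform()`):
the least deprived area receives scaled rank $R = 1/N$ and the most deprived
$R = 1$, and

$$X = -23\,\ln\!\big\{1 - R\,[1 - e^{-100/23}]\big\},$$

which maps $(0, 1]$ onto $(0, 100]$ with $X = 100$ exactly at $R = 1$. The
constant 23 stretches the deprived tail: the top of the distribution is
spread out (so the most excluded areas are finely separated) while the rest
is compressed. Ties in the raw scores receive consecutive ranks in stable
area-id order rather than averaged ranks; this keeps $R$ exactly on the grid
$k/N$ and preserves the algebraic identity $X(1) = 100$, at the cost of an
arbitrary (but deterministic and documented) ordering within ties. The
composite index is the arithmetic mean of the five transformed domain
indices; it is *not* rank-transformed a second time.

### Population-weighted quintiles

Quintiles contain 20% of *children*, not 20% of areas
(`weighted_quintiles()`). Areas are sorted by the basis value descending
(ties broken by area id), the cumulative child population is computed, and an
area joins quintile $k$ when the midpoint of its cumulative-weight interval
lies in $((k-1)/5,\ k/5]$ of the total. The midpoint rule is deterministic,
independent of how boundary areas are ordered among equals, and bounds each
quintile's deviation from 20% by a single area's population share. The
comparison is carried out in the unscaled cumulative-weight space
($5m$ vs $k\,W$ rather than $m/W$ vs $k/5$) so integer populations are
compared exactly at the boundaries. Quintile 1 always holds the areas with
the largest basis values — the highest risk (index) or the worst outcomes
(PPH rate).

## Health outcome measures

**Hospitalisation rates** (`mean_annual_pph_rate()`) are directly
age-standardised rates per 1,000 children 0–14 per year. For each financial
year the December population of each age group (0–4, 5–9, 10–14) is
interpolated as the mean of the adjacent June estimates; the yearly rate is
$1000 \sum_g s_g\, c_g / n_g$ with $s_g$ the standard population's age
shares; and the area's rate is the unweighted mean of the yearly rates over
the three years analysed (an "average annual rate", damping small-area
stochasticity). Whether a multi-year rate should be a mean of yearly
standardised rates or a standardised rate of pooled counts is a genuine
choice; the mean of yearly rates is used as it is what "average annual rate"
describes. The standard population's shares are a required input
(`standard_population()`); the default is a clearly labelled synthetic
placeholder (0.32/0.33/0.35), because the true 2001 national standard is not
distributed with this package and inventing census figures would be worse
than requiring them.

**Avoidable mortality** is too rare for area-level rates (most areas record
zero or one death in a year; areas with no recorded deaths are taken to have
had none). The analysis therefore pools one year of deaths within each
quintile (`quintile_death_rates()`): the quintile rate is total deaths over
total 0–14 population, and that rate is applied to the quintile's 0–15
population (the population used to build the quintiles) to estimate deaths
among 0–15 year olds. The small 0–14 vs 0–15 mismatch reflects differing
coding conventions in the source collections; both populations are carried
explicitly and never imputed from each other.

## Association and models

* `weighted_pearson()` — Pearson correlation with areas weighted by their
  0–15 child population.
* `crosstab_shares()` — 5×5 cross-tab of outcome quintile by index quintile,
  each cell the percentage of all children; the diagonal sum is the share of
  children whose two quintiles agree, the diagonal-plus-adjacent sum allows a
  one-quintile discrepancy. Percentages are rounded (one decimal) only at the
  reporting layer; all statistics are computed unrounded, which is why a
  diagonal sum can differ by ±0.1–0.2 from the sum of separately rounded
  cells.
* `quintile_summary()` — unweighted per-quintile mean, sample SD, min, max of
  area rates: Dispersion across areas is the quantity of interest here, so no
  population weighting.
* `gradient_tests()` — one-way ANOVA across quintiles, complemented by
  Kruskal–Wallis and all-pairs Welch t-tests because the most disadvantaged
  quintile typically has far higher variance than the rest.
* `fit_polynomial()` — OLS of area rate on raw powers of the composite index
  (up to cubic), followed by backward elimination: repeatedly drop the
  non-intercept term with the largest p-value ≥ α (default 0.05) and refit,
  until all remaining terms are significant. Backward-only elimination from
  the full cubic, with the intercept always retained, is the most literal
  reading of "stepwise elimination to a model with only significant terms";
  raw (non-orthogonalised) powers keep coefficients on the natural index
  scale.
* `residuals_by_remoteness()` — residual summaries by the five-level
  remoteness classification, one-way ANOVA, and Tukey–Kramer all-pairs
  comparisons (the Kramer form because category sizes are very unequal).
  Areas spanning several categories are assigned by population majority, with
  ties resolved to the more remote category (`assign_remoteness()`, with a
  warning).
* `mortality_chi_square()` — Pearson chi-square on the 5×2 deaths/survivors
  table, df = 4, *without* continuity correction: the no-correction form is
  what reproduces the published domain statistics from their printed counts.

## The synthetic data generator

`simulate_cse_data()` draws, per area: a latent disadvantage factor
$z \sim N(0, \sigma_z)$; 13 indicators loading positively on $z$ (logistic
link for proportions, $\text{base} \cdot e^{-(\lambda z + \varepsilon)}$ for
the three access ratios, so higher disadvantage means worse access); a
log-normal child population; a five-level remoteness category; Poisson
hospitalisation counts per year and age group with log rate
$\beta_0 + \beta_1 z + \gamma_{\text{remoteness}}$ against the interpolated
December population; and Poisson death counts with rate
$\mu \cdot e^{\delta z}$ per 100,000.

Default study conditions (chosen once, before any testing against them):
1154 areas (the national analysed-area count); unit loadings and latent SD 1;
indicator noise SD 0.5 (strong but not deterministic loadings);
child populations LogNormal(meanlog 8, sdlog 0.8) — right-skewed, ≈ 4.1 M
children nationally; remoteness probabilities (0.34, 0.24, 0.26, 0.08, 0.08)
matching the frequencies of the five categories among analysed areas;
baseline hospitalisation rate $e^{\beta_0} = 0.024$ events per child-year
(≈ 24 per 1,000), disadvantage slope 0.35, remote excess 0.5 on the log scale
for Remote and Very remote only; 23 avoidable deaths per 100,000 child-years
(≈ 880 deaths nationally per year) with disadvantage slope 0.3; three years
of data.

The generator reproduces the *structure* the analysis assumes — one dominant
disadvantage factor, monotone indicator loadings, count outcomes with a
remote excess — and deliberately not the texture of real census data: no
spatial autocorrelation between neighbouring areas, no realistic non-response
mechanism (non-response fractions are independent Beta draws, with a switch
to force a stated number of filter failures), no overdispersion beyond
Poisson, and no Indigenous-status structure. Passing the recovery tests
therefore shows the pipeline is correct and well-calibrated under its own
assumptions, not that those assumptions hold in any particular census.

One caution discovered while validating the generator: because the
hospitalisation rate is log-linear in $z$, the *linear* (Pearson) correlation
between $z$ and the crude rate increases with the disadvantage slope only up
to a point; at slopes well beyond the default the convexity of the
exponential starts to reduce it again. The monotonicity test therefore covers
the generator's operating range (slopes 0–0.35).

## Numerical choices and degenerate inputs

* **Exact fits.** With noise-free rates the residual variance is zero and
  t-based p-values are undefined (0/0). `fit_polynomial()` detects
  RSS/TSS < 1e-10 and switches to an exact-fit criterion: a term is dropped
  iff the model without it still fits exactly (highest removable power
  first). This makes recovery of a noise-free polynomial law exact and
  deterministic. Constant rates collapse directly to the intercept-only
  model.
* **Zero-variance ANOVA.** If all residuals are identical,
  `residuals_by_remoteness()` reports F = 0, p = 1 by convention instead of
  0/0.
* **Backward elimination under pure noise.** With three strongly collinear
  raw powers, the familywise probability that some term survives elimination
  at α = 0.05 is ≈ 13% (measured by simulation at n = 500), noticeably above
  the single-test 5%; the tests assert the large-majority collapse rate this
  implies, not a naive 95%.
* **Boundary exactness.** $X(R{=}1) = 100$ to 1e-9 is asserted over
  $N \in \{5, 100, 1154\}$; quintile boundary comparisons are done in
  unscaled weight space so integer populations are exact.
* **Ties.** Rank ties: consecutive ranks in stable area-id order. Quintile
  basis ties: sorted by area id. Remoteness ties: more remote category, with
  a warning.
* **Singleton remoteness categories** are excluded from Tukey comparisons
  (with a warning) but retained in the summary table and ANOVA.

## Problem sizes in the test and acceptance runs

Unit tests run on fixtures of 3–80 areas against brute-force oracles
(cumulative-interval enumeration for quintiles, direct sums for weighted
correlation and standardisation, closed-form Welch t, the Pearson chi-square
formula, explicit eigen-decomposition for PCA). Recovery tests use 1,000
areas — large enough that the weighted correlation between composite index
and latent factor stabilises well above the 0.8 criterion — and the
acceptance script runs the full pipeline once at the default 1,154 areas.
The published quintile-level inputs are 5×5 and 5×2 tables and validate
desk-scale: diagonal concordance sums, the five domain chi-squares, and the
extreme-quintile gap in estimated deaths. The composite-index chi-square
computed from the printed quintile counts is ≈ 49.1, not the published 49.9
(the published figure was likely computed from unrounded estimated deaths);
it is kept as a frozen regression value rather than silently "corrected".

## Known limitations

* The index is only as good as its indicators; the health-services domain in
  particular (provider-to-population ratios) ignores cross-area travel and
  shows the weakest association with outcomes in published national results.
* Quintile-level mortality pooling cannot localise risk below the quintile.
* The generator's independence assumptions (no spatial structure, Poisson
  counts) make synthetic confidence statements optimistic relative to real
  data.
* Area aggregation upstream of the inputs (merging atypically small areas) is
  out of scope: input areas are taken as final.
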
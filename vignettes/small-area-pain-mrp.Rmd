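---
title: "Small-area estimation of chronic pain prevalence by multilevel regression and poststratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of chronic pain prevalence by multilevel regression and poststratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Health surveys are far too small to estimate outcome prevalence directly in
a neighbourhood of ~1,500 residents: a survey of ~4,000 respondents spread
over 298 LSOAs (lower layer super output areas) leaves a dozen respondents
per area. `painscape` implements the standard answer, multilevel regression
and poststratification (MRP), for two binary outcomes defined on adults
aged 35 and over:

* **chronic pain** — pain on most days or every day in the past 6 months;
* **high-impact chronic pain** — chronic pain that also limited life or
  work activities on most days or every day; by definition a subset of
  chronic pain.

The package is synthetic-first: it ships a generator that emulates a
three-local-authority English study region (Stoke-on-Trent,
Newcastle-under-Lyme, Staffordshire Moorlands; 298 LSOAs; 275,391 residents
aged 35+) with known ground-truth parameters, so every stage of the
pipeline can be validated by parameter-recovery simulation rather than by
unavailable survey microdata.

## The model

Individual outcomes are modelled by a two-level logistic regression,

$$\operatorname{logit} P(Y_{ij} = 1) = \beta_0 + x_{ij}'\beta + u_j,
\qquad u_j \sim N(0, \sigma^2_u),$$

with fixed effects for

* the 12-level age-sex interaction (six age groups 35–44 … 85+ crossed with
  sex; reference: men 35–44), an individual-level term;
* IMD (index of multiple deprivation) decile of the LSOA, deciles 1–9
  against the most affluent decile 10 as reference;
* a rural/urban indicator (reference: urban);
* optionally, mean-centred HADS depression score and/or BMI in sensitivity
  models;

and an LSOA random intercept $u_j$.  The displayed model is linear on the
log-odds scale; the logistic link is the natural choice for binary outcomes
and is stated explicitly because prevalence predictions depend on it.

Fitted cell probabilities are **poststratified**: for each LSOA × age-sex
cell with known population count $n_c$, the predicted probability $p_c$ is
the posterior mean of $\operatorname{invlogit}(\beta_0 + x_c'\beta + u_j)$
over posterior draws (the mean of the inverse logit, not the inverse logit
of the posterior mean — the nonlinear link makes the difference a genuine
bias, not a rounding detail).  The prevalence of any geography is then
$100 \sum n_c p_c / \sum n_c$ over its cells, which makes LA and regional
estimates exactly consistent with their LSOAs by construction.

### Unrepresented areas

LSOA varying effects are estimated only where respondents exist.  The
default prediction policy (`posterior_mean_zero_fill`) sets $u_j = 0$ for
unrepresented LSOAs, i.e. applies the coefficients with the varying effect
only where the area was represented.  This shrinks unrepresented areas
toward the profile predicted by their demographics and deprivation; the
alternative `integrate_draws` policy instead draws fresh $u_j \sim N(0,
\sigma^2_u)$ per posterior draw, propagating between-area heterogeneity at
the cost of extra Monte-Carlo noise.  Zero-fill is the default because it
matches the estimand "expected prevalence for an area with these observed
characteristics".

### Priors and samplers

Two fitters share one output contract (`pain_fit`), so everything
downstream is fitter-agnostic:

* `fit_mcmc()` — Gibbs sampling with Pólya-Gamma data augmentation.  Each
  observation receives a PG(1, ψ) latent variable, making β and u
  conditionally Gaussian; all updates are exact conditional draws with no
  tuning parameters, which is why this augmentation mixes well for logistic
  mixed models.  Priors are weakly informative: Normal(0, 10²) on fixed
  effects and half-Cauchy(0, 5) on σ_u (sampled via its inverse-gamma
  mixture representation; an inverse-gamma prior on σ²_u is available in
  `model_spec()` for sensitivity to that choice, which no analysis of this
  kind should leave unexamined).  The PG sampler itself is Devroye's
  alternating-series rejection sampler, implemented in C++ and driven by
  R's RNG so `set.seed()` governs everything.
* `fit_approximate()` — penalised-likelihood point estimation via
  `lme4::glmer` (`nAGQ = 0`).  It returns the same object shape with
  degenerate one-draw "posteriors".  It is an approximation — no posterior
  uncertainty, mode-based variance — but it is deterministic and roughly two
  orders of magnitude faster, which is what makes bootstrap loops feasible
  on a desk machine.  Fixed-effect estimates from the two fitters agree to
  well under 0.1 log-odds on the default synthetic region.

Desk-scale MCMC defaults are 2 chains × 2,000 burn-in × 5,000 stored
iterations; production analyses of this kind historically used runs two
orders of magnitude longer, and those settings remain available through
`model_spec()`.  Convergence is gated (split-chain potential scale
reduction < 1.05, effective sample size > 400 on every reported parameter);
failures warn and are recorded in the fit's `$diagnostics`, never silently
ignored.

### Residual variance

`compute_vpc()` reports the share of residual latent propensity variance
attributable to unobserved LSOA characteristics under the latent-threshold
formulation, $\sigma^2_u / (\sigma^2_u + \pi^2/3)$, where $\pi^2/3$ is the
standard-logistic individual-level variance.  This is the conventional
variance partition for multilevel binary models; published residual-variance
percentages of this kind do not always state their formula, so exact
numerical agreement with any particular report cannot be assumed — the
formula here is explicit and tested.

## Ethnicity correction

Survey samples from a ~91%-White region cannot support individual-level
ethnicity terms.  Instead, poststratified LSOA estimates are multiplied by
a proportion-weighted blend of published relative-prevalence factors
(relative to White populations): chronic pain — Asian excluding Chinese
1.1, Black 1.2, Chinese 0.9, Mixed/multiple 1.0; high-impact — 1.2, 1.5,
0.8, 1.1.  The blend $\sum_g \pi_{gj} f_g$ is the minimal combining rule
consistent with "group prevalence = White prevalence × factor".  Correction
is applied at LSOA level and re-aggregated upward (the alternative —
correcting after aggregation — differs only through within-geography
covariance of ethnicity mix and prevalence, and is not what a small-area
correction is for).  Corrected values are truncated at 100% with a warning,
since a multiplicative correction is unbounded in principle.  On the default
region the correction moves LSOA estimates by roughly −0.05 to +3
percentage points, concentrated in the most diverse neighbourhoods.

## Bootstrap confidence intervals

`bootstrap_estimates()` re-runs the whole chain — refit, poststratify,
correct — on each resampled dataset and forms per-LSOA percentile intervals
(linear-interpolation quantiles, fixed as such for reproducibility).
Choices that the method itself does not dictate, made once and documented:

* **Resampling unit**: respondents within LSOA (stratified), preserving
  per-LSOA sample sizes so the random-effect structure is comparable across
  replicates; pooled resampling is available for comparison.
* **Fitter in the loop**: `fit_approximate` by default; full MCMC per
  replicate is available but is a production-cluster setting, not a desk
  one.
* **Degenerate replicates**: an LSOA that loses all its respondents in a
  replicate falls back to the unrepresented-area policy; replicates whose
  fit fails are logged and skipped, and more than 10% failures aborts the
  run because silently dropping replicates would bias the intervals.
* Replicate seeds derive deterministically from the bootstrap seed:
  identical settings give bit-identical intervals.

Percentile intervals at a dozen respondents per area are approximate; in
recovery simulations on the default region, nominal 95% intervals cover the
true LSOA prevalence for ~90% of areas, which is the level of honesty the
percentile method can offer at this n (and the reason interval widths of
tens of percentage points are reported rather than hidden).

## Inequality summaries

LSOAs are ranked across the whole region and split into five rank-based
quintile groups as equal as possible (sizes differ by at most one; 298
LSOAs split 60/60/60/59/59), with ties broken deterministically by LSOA
code.  Rank-based assignment guarantees the balanced sizes that "quintile"
implies regardless of ties, which value cut-points do not.  Per local
authority the package reports quintile counts, the **20:20 metric** —
(highest-quintile count − lowest-quintile count) / LSOA count — the median
and range of LSOA estimates, and the max/min fold variation (undefined, not
infinite, when the minimum is 0).

The 20:20 value is reported as an absolute value with the signed value
alongside: published tables of this statistic print magnitudes even for
authorities dominated by low-quintile areas (where the raw formula is
negative), and the sign is information worth keeping, so both are emitted.

## The synthetic region: what it does and does not emulate

`geography_spec()` defaults encode the emulated study region: LSOA counts
159/80/59 and 35+ populations 136,718/74,399/64,274 across the three
authorities; a heavily deprived, almost entirely urban first authority
(30% of its neighbourhoods in the most deprived national decile) against
more affluent, partly rural neighbours; around 10 of 298 LSOAs in the most
affluent decile; and Dirichlet-drawn ethnicity proportions averaging ~91%
White with a configurable minority of diverse LSOAs.  Population totals are
apportioned exactly (largest-remainder rounding), so conservation checks are
exact rather than approximate.

`true_parameters()` defaults are generator configuration, not published
estimates: log-odds chosen so crude prevalence rises with age, is higher in
women, falls with affluence, and is lower in rural areas, approximating the
crude pattern of the emulating survey.  The default between-LSOA variance
is σ²_u = 0.1432 — the value implied by a 4.17% latent-threshold variance
partition, the residual-variance share reported for the rarer outcome in
the emulated study.  The chronic-pain-implied value (~0.032, from 0.96%)
is so small that area effects would be barely identifiable at survey scale;
anchoring the default at the identifiable value makes recovery testing
meaningful, and σ²_u is a single argument for anyone who wants the smaller
regime.

The sampling chain multiplies a 21% sample rate, a 14.6% practice-frame
coverage and a 51.9% usable-response rate, with ~5% missing outcome data
injected completely at random, landing the complete-case sample near the
emulated survey's ~4,150.  High-impact pain is generated as a second
Bernoulli conditional on chronic pain with age-sex-specific conditional
probabilities (rising from ~0.25 in younger men to ~0.6 at 85+), which
guarantees the definitional nesting of the outcomes.

Deliberate simplifications, hence what passing tests do **not** show about
real data: missingness is MCAR (the emulated analysis is complete-case and
makes no missingness-mechanism claim); response propensity is flat in age
and outcome (real surveys over-represent older respondents); there is no
spatial autocorrelation between neighbouring LSOAs; rurality and
deprivation are drawn independently within authority; LSOA codes are
opaque synthetic strings.  The marginal high-impact model fitted by the
pipeline is also mildly misspecified relative to the conditional generator
— deliberately so, since the real analysis fits the two outcomes
separately too.

## Numerical and testing choices

Problem sizes used by the test suite, chosen as the smallest that make the
statistical assertions meaningful: recovery simulations use the full 298
LSOA region with ~8,000 respondents (a 13.9% frame coverage with full
response), 20 survey replicates, and MCMC at 2 chains × (500 burn-in +
1,000 stored) — the Pólya-Gamma sampler's mixing makes longer chains
unnecessary for interval-coverage checks at test tolerances.  Bootstrap
checks use 200 replicates at survey scale (coverage), 60 (width scaling)
and 40 (determinism).  Unit tests run on a 40-LSOA two-authority region.

Recovery results worth knowing when interpreting fits: individual-level
(age-sex) coefficients are recovered with mean bias under 0.05 log-odds,
but area-level coefficients (IMD, rural) show a systematic ~0.05–0.08
attenuation at ~27 respondents per LSOA because group-level covariates
compete with the group random intercept — a finite-sample property of
multilevel models, shared by the penalised-likelihood fitter, that
disappears as per-area n grows.  σ²_u itself is recovered within a few
percent at study scale.

Degenerate inputs are handled explicitly: a single represented LSOA is
rejected (between-area variance unidentifiable); complete separation in a
category warns and lets the prior carry the coefficient; categories with no
respondents keep their design column (MCMC) or get coefficient 0 with a
warning (penalised fit, where the column is dropped as rank-deficient);
zero-population geographies and missing cell probabilities are errors, not
NAs.  All randomness flows from one master seed through
`derive_seed(seed, stream)`, so stages are individually reproducible and
pipeline reruns are byte-identical.

## Pipeline and file formats

`run_pipeline()` sequences simulate → preprocess → fit → poststratify →
bootstrap → inequality → report, reading any missing stage inputs from the
output directory so stages can run in separate sessions (a fit reloaded
from CSV carries posterior means only — rerun fit and poststratify in one
call if full-posterior prediction matters).  All interchange files are
plain CSV with one `#` provenance header line (config hash + seed);
`validate_schema()` checks column presence, closed vocabularies and numeric
ranges and reports *every* violation with file, row and column.
`estimates.csv` is keyed by LSOA/MSOA/LA codes for external joining to
boundary files; the package deliberately renders no maps.

```{r example}
library(painscape)
cfg <- pipeline_config(output_dir = "painscape_out", seed = 7,
                       bootstrap = bootstrap_spec(n_replicates = 200))
run_pipeline(cfg)
```

A thin command-line front-end over the same functions ships in
`inst/cli/painscape.R`.

## Known limitations

* Percentile intervals only; BCa or studentised intervals are out of scope,
  as is a parametric bootstrap from posterior draws.
* One random-effect level (LSOA); no crossed or spatial (CAR/BYM)
  structures.
* The ethnicity correction assumes the published factors transfer to the
  region and ignores within-LSOA confounding of ethnicity with age and
  deprivation; it is a bias patch, not a model.
* The approximate fitter understates σ²_u somewhat at survey scale (a
  known property of `nAGQ = 0`); the MCMC fitter is the reference.
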
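---
title: "Methods: zone-level spatial analysis of anthropometric failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-level spatial analysis of anthropometric failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciafspatial)
```

## The problem

National prevalence figures for child undernutrition hide large differences
between administrative zones. This package implements the zone-level
workflow used to study that heterogeneity: classify each under-five child by
the Composite Index of Anthropometric Failure (CIAF), aggregate to zones,
test for spatial clustering with Moran's I and LISA statistics, and explain
the zone-level risk surface with the nested family of Gaussian spatial
regression models, compared by AIC/BIC.

## CIAF classification

A child with height-for-age (HAZ), weight-for-age (WAZ) and weight-for-height
(WHZ) z-scores fails on an index when the z-score is strictly below the
cutoff (default −2 SD). The strict inequality is deliberate: the
conventional definition reads "< −2 SD", so a child exactly at −2 is not
counted as failing; the cutoff is configurable. The three booleans
(wasting = WHZ, stunting = HAZ, underweight = WAZ) produce eight
combinations:

| code | wasting | stunting | underweight |
|------|---------|----------|-------------|
| A    | no      | no       | no          |
| B    | yes     | no       | no          |
| C    | yes     | no       | yes         |
| D    | yes     | yes      | yes         |
| E    | no      | yes      | yes         |
| F    | no      | yes      | no          |
| Y    | no      | no       | yes         |
| X    | yes     | yes      | no          |

CIAF = 1 for every code except A. The combination wasting + stunting
without underweight is anthropometrically unusual and absent from the
classical A–Y roster; we assign it its own label X rather than silently
folding it into another category, so roster-faithful tallies can always be
recovered while CIAF still means "at least one failure". Children with any
missing z-score are removed listwise; |z| > 6 triggers a plausibility
warning and |z| > 10 a hard exclusion (both configurable — published
surveys rarely state their exact cleaning rule, so the screen is explicit
and tunable here).

## Expected counts and relative risk

With `y_i` CIAF cases among `n_i` children in zone i, the expected count is
`E_i = n_i * (Σy / Σn)`, so `ΣE = Σy` exactly, and the crude relative risk
(standardized morbidity ratio) is `rr_i = y_i / E_i`, whose E-weighted mean
is 1. The models are fitted to a transform of this surface; the default
response is `log(rr_i)`, which keeps the expected-count machinery
meaningful, is symmetric around 0, and back-transforms to a risk ratio.
Prevalence and logit-prevalence responses are available; the transform used
is recorded in every fit. A zero count makes log-rr undefined and is
reported as an error rather than patched with a continuity correction.

## Spatial weights

Queen contiguity (any shared boundary point) is the default, with rook
(shared boundary segment) and explicit edge lists as alternatives.
Contiguity predicates are exact on the input coordinates with no snapping:
programmatically generated lattices are exact by construction, and real
boundary files should be topologically cleaned before use. Islands are
errors by default, because every likelihood below assumes each zone
interacts with neighbors; a keep-zero-row policy exists for synthetic edge
cases. GAL neighbor lists and GeoJSON FeatureCollections are the exchange
formats.

Model likelihoods require row-standardized W. Row standardization of a
symmetric binary adjacency gives a matrix similar to the symmetric
`D^-1/2 A D^-1/2`, so its spectrum is real; the spectrum is computed once,
cached on the weights object, and reused for every log-determinant below.
Moran's I accepts either style, since the `n/S0` prefactor normalizes both.

## Moran's I and LISA

Global Moran's I is `(n/S0) Σij w_ij z_i z_j / Σ z_i²` with `z = x − x̄`,
`E[I] = −1/(n−1)` under the null. Inference defaults to permutation with
999 shuffles and an explicit seed; the classical randomization and
normality variances are computed alongside and drive the analytic z and
two-sided p. The pseudo p is folded to the observed side of E[I] by
default; a fixed-direction (`"greater"`/`"less"`) and a two-sided variant
are exposed, because a folded p is the natural report for a single observed
statistic while the fixed-direction p is the one that is uniform under the
null (the property our validation suite checks).

Local Moran `I_i = (z_i/m2) Σ_j w_ij z_j` uses conditional permutation
(value at i held fixed, the remaining n−1 values shuffled into the
neighbor positions), the standard LISA construction. Cluster labels
(high-high, low-low, high-low, low-high) are assigned when the pseudo p is
at or below α = 0.05 by default, with no multiplicity correction — matching
common practice for LISA maps — and an optional Benjamini–Hochberg step for
stricter work.

## The model family

With A = I − ρW and B = I − λW, the most general member (GNS) is

    y = ρ W y + X β + W Z θ + u,    u = λ W u + ε,    ε ~ N(0, σ² I)

and its log-likelihood is

    ℓ = −(n/2) log(2πσ²) + log|A| + log|B| − ‖B(Ay − X̃γ)‖² / (2σ²)

with X̃ = [X, WZ] and γ = (β, θ). Fixing ρ = 0, λ = 0 and/or θ = 0 yields
SDM, SDEM, SAC, SAR, SEM, SLX and OLS. Z defaults to all of X (a
configurable subset), and the spatial coefficients are restricted to
`(1/ω_min + ε, 1 − ε)` where ω_min is the smallest eigenvalue of the
row-standardized W — an interval that admits the strongly negative error
coefficients occasionally seen in applied work.

Estimation is by concentrated likelihood: for fixed spatial coefficients, γ
and σ² have closed-form maximizers, so OLS/SLX are direct solves, SAR/SDM
and SEM/SDEM are bounded one-dimensional searches (tolerance 1e-9), and
SAC/GNS are L-BFGS-B searches over (ρ, λ) started deterministically from
the center and the four 5 %-inset corners of the admissible box *plus* the
two nested one-coefficient optima `(ρ̂_lag, 0)` and `(0, λ̂_err)`. The warm
starts cost two cheap scalar searches and guarantee, by construction, that
the two-coefficient families never score below the one-coefficient families
they nest — the monotone chains OLS ≤ SAR ≤ SDM ≤ GNS, OLS ≤ SEM ≤ SDEM ≤
GNS, SAR ≤ SAC ≤ GNS and OLS ≤ SLX ≤ SDM then hold to optimizer precision.
All starts are deterministic, so fits are bit-reproducible.

`log|I − cW|` is evaluated as `Σ log(1 − c ω_i)` over the cached spectrum;
the validation suite pins this against dense determinants to 1e-10.
Standard errors invert the numerical Hessian (central differences, relative
step 1e-5) of the full negative log-likelihood at the optimum; a
non-positive-definite Hessian is reported as an error naming the likely
flat/boundary optimum, and GNS fits carry an explicit weak-identification
warning when the Hessian condition number exceeds 1e8 — GNS is known to be
poorly identified on small lattices, which is why applied comparisons often
leave it out of the final ranking.

The parameter count k includes every regression coefficient, each active
spatial coefficient, and σ². Including σ² shifts all AICs by a constant and
therefore never changes a ranking, but makes the values comparable with
other software that counts it. Ties in AIC (below 1e-6) break by BIC, then
by parsimony.

## The pipeline

`run_full_analysis()` chains classification (for child-level input),
expected counts, weights, a pairwise-correlation screen (|r| ≥ 0.8 flags a
warning but never drops a covariate — that is an analyst's decision),
global Moran, LISA, the requested fits, the AIC ranking, and the crude vs
fitted relative-risk surface. The Moran gate is advisory by default: if the
permutation p exceeds α the pipeline warns and continues, so spatially
unstructured data still produce the OLS baseline column. All permutation
stages derive their seeds from the single config seed with documented
offsets (+1 global Moran, +2 LISA). For families with a response lag the
fitted surface is the reduced-form mean `(I − ρ̂W)^{-1} X̃γ̂`; error-family
fits predict through `X̃γ̂`.

## The synthetic study

Because the survey microdata that motivated this design are
access-restricted, the package ships a generator that emulates their
structure at desk scale; it is first-class, tested code, and its defaults
are the package's study conditions:

- 72 zones on a regular 9 × 8 unit-square lattice with queen contiguity.
  (A mildly irregular partition would be marginally more realistic, but the
  exact-coordinate contiguity predicate would not register partially
  overlapping edges, so regularity is the honest choice here.)
- Six spatially smoothed percentage covariates, `(I − φW)^{-1}ε` columns
  with φ = 0.6, affinely mapped to percentage-like ranges (constants
  recorded as attributes).
- A log relative-risk surface drawn from the SAC process with ρ = λ = 0.4
  and σ = 0.15 on the standardized covariates, anchored at a 45 % overall
  prevalence — a realistic national under-five CIAF figure for the emulated
  setting.
- 200 children per zone whose trivariate (HAZ, WAZ, WHZ) z-scores use
  correlation 0.6 (HAZ–WAZ, WAZ–WHZ) and 0.1 (HAZ–WHZ), the typical survey
  pattern; each zone's common mean shift is chosen by monotone inversion so
  the zone's marginal failure probability matches its target prevalence.

What the generator does *not* emulate: two-stage cluster sampling, survey
weights, non-response, age–sex structure within zones, or raster-derived
geospatial covariates. Tests that pass on this generator therefore validate
the statistical machinery (classification, weights, autocorrelation,
likelihoods, selection), not the survey-design corrections a real analysis
would also need.

## Validation problem sizes

The validation suite exercises the estimators at the sizes a desk check
supports: Moran oracles on random graphs up to n = 12 (500 instances),
permutation-null uniformity over 2,000 replicates at 199 permutations,
log-determinant identities on 50 random graphs up to n = 50, likelihood
nesting on a 15 × 15 lattice, parameter recovery with 200 replicates on
15 × 15 (SAR ρ = 0.5 and SEM λ = 0.5, bias within 0.05 and Wald coverage
inside [0.90, 0.98]), and AIC selection under a SAC process with 100
replicates at n = 400, where SAC wins a clear majority. The
`scripts/acceptance.R` script recomputes these summaries from scratch.

## Known limitations

- The Gaussian likelihoods treat the response transform as exact;
  small-count zones make log-rr noisy, and a Poisson/CAR treatment is out
  of scope here.
- Impact (direct/indirect effect) decompositions for lag models are not
  computed.
- The spatio-temporal dimension (survey rounds) is carried as a label only.
- GNS estimates are reported but weakly identified at n ≈ 72; rely on the
  information criteria, which in our experiments consistently prefer the
  more parsimonious true family.
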
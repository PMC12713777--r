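---
title: "Methods: from chamber time series to CO2-equivalent budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chamber time series to CO2-equivalent budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemflux)
```

stemflux implements the computational chain used in chamber-based
greenhouse-gas (GHG) studies of forested wetlands — mangroves in
particular — where tree stems are an overlooked pathway for methane
(CH4) and nitrous oxide (N2O) alongside the soil surface. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

## 1. Chamber fluxes

A static chamber encloses a patch of stem bark, soil, or water
surface; the analyzer records headspace concentration over a closure
of roughly five minutes. The flux is inferred from the slope *S* of
the ordinary least-squares regression of concentration on time
(`fit_slope()`), converted to areal units by the ideal-gas headspace
inventory at 1 atm:

$$F = S_{x} \cdot \frac{V}{R\,T} \cdot M \cdot \frac{3600 \times 1000}{A}
\quad [\mathrm{mg\,m^{-2}\,h^{-1}}]$$

where $S_x$ is the slope as a mole fraction per second (ppm s^-1 for
CO2, ppb s^-1 for CH4/N2O, declared per series and never inferred),
*V* the chamber volume (L), *A* the enclosed area (m^2), *T* the
chamber air temperature (K), *M* the gas molar mass (44.01, 16.04,
44.01 g mol^-1 for CO2, CH4, N2O) and *R* = 0.082 L atm K^-1 mol^-1.
The compact flux formula often printed for this method omits *M* and
the 1 atm pressure; the form above is the only dimensionally
consistent reading that yields mg m^-2 h^-1, and it is what
`compute_flux()` implements. *R* is kept at the conventional printed
value 0.082 rather than 0.0820574; the 0.07 % difference is far below
chamber measurement uncertainty, and the constant is an argument for
anyone who prefers the precise value.

**Quality control.** A deployment is rejected when the regression
R^2 falls below 0.7. The boundary is read strictly: R^2 = 0.7 passes.
A flat series has an undefined R^2 (zero concentration variance);
`qc_filter()` fails it with the distinct reason `"degenerate"` instead
of passing a spurious zero flux. QC is applied per gas per deployment,
since the same closure can yield a clean CO2 trace and a noisy N2O
trace. Rejected records are carried through with `qc_pass = FALSE` and
excluded from every aggregation.

Chamber geometry helpers (`chamber_area_volume()`) cover the designs
used in the field: a 30 cm semicircular soil cover (6.4 L) on a 16 cm
steel ring, stem chambers enclosing an arc-width x height bark patch,
and a floating chamber. The ring insertion depth is not a measured
quantity in most campaigns; it defaults to 10 cm (leaving 6 cm of
ring headspace) and is configurable, because the headspace volume —
not the cover volume alone — enters the flux equation.

## 2. Hierarchical upscaling

Stem fluxes are measured at height intervals (e.g. 0–40, 40–80,
80–120, 120–200 cm above ground). Upscaling proceeds in three
steps:

* per tree: $F_t = \sum_x F_x P_x H_x$ (mg tree^-1 h^-1), with $P_x$
  the stem perimeter at the interval and $H_x$ its height
  (`per_tree_flux()`);
* per unit stem area: $F_{ta} = F_t / A_t$ (`stem_area_weighted()`),
  where $A_t$ defaults to the summed sampled lateral area
  $\sum P_x H_x$ when no independent allometric total is supplied — a
  deliberate choice, since campaigns record perimeters, not frustum
  profiles;
* per forest hectare and year:
  $F_{taw} = \sum_s \bar F_{t,s}\, d \times 10^{-6} h_s$
  (`forest_area_weighted_stem()`), with *d* the tree density
  (trees ha^-1) and $h_s$ the hours assigned to season *s*.

Seasons default to equal quarters of an 8760-hour year (2190 h each),
so a constant per-tree flux *f* annualizes to $f\,d \times 8.76
\times 10^{-3}$ kg ha^-1 yr^-1. Calendar-weighted seasons can be
passed via `hours_per_season`. Campaigns spanning more than four
seasonal visits are reduced by averaging duplicate season labels
before annualization, so the year is counted exactly once. Soil
fluxes follow the same seasonal logic over 10^4 m^2 ha^-1
(`forest_area_weighted_soil()`); the ecosystem total is the sum of
the stem and soil pathways, and the stem contribution
$100 F_{taw}/(F_{taw}+F_{saw})$ may legitimately be negative or
exceed 100 % when the two pathways have opposite signs — stem N2O
emission over a soil N2O sink is a real configuration, not an error.
Negative fluxes (uptake) are retained sign-faithfully everywhere; a
zero total flags the contribution undefined rather than dividing by
zero. The same guard applies to `vertical_contributions()` (per-
interval shares of $F_t$, which sum to exactly 100 %) and to seasonal
shares when opposing seasons cancel.

## 3. CO2-equivalent budgets and burial offsets

Annual CH4 and N2O fluxes are expressed as CO2 equivalents with
GWP100 weights from IPCC AR6 (CH4 = 27, N2O = 273; `gwp_table()` makes
them explicit and overridable):

$$E = (F_{taw,\mathrm{CH_4}}\,\mathrm{GWP}_{\mathrm{CH_4}} +
      F_{taw,\mathrm{N_2O}}\,\mathrm{GWP}_{\mathrm{N_2O}})
      \times 0.001 \times A_f \quad [\mathrm{t\,CO_2e\,yr^{-1}}]$$

Soil carbon burial (t C yr^-1) converts to CO2e by the molar-mass
ratio 44.01/12.011 ≈ 3.664 (`burial_to_co2e()`); the offset
percentage is 100 x stem CO2e / burial CO2e, scale-invariant and
undefined-flagged at zero burial. Published tables of this arithmetic
can contain transposed rows — when a printed total disagrees with the
total recomputed from its own printed components, `site_budget()`
reports the self-consistent value; it does not guess which printed
column was at fault.

**Global first-order estimate.** `global_upscale()` multiplies
quantiles of a pooled per-tree flux distribution by a global mean
tree density (default 263.68 trees ha^-1) and mangrove area (default
145 608 km^2) and 8760 h. The median and quartiles are used because
per-tree fluxes are strongly right-skewed; the default pool is all
trees x seasons across species, with per-species pooling available by
filtering the pool upstream. The quantile rule is `stats::quantile`
type 7 (linear interpolation, R's default); no single convention is
universal, so the type is an argument. The uncertainty of such an
estimate is dominated by the assumption that all forests emit at the
sampled rates, which no quantile rule fixes.

## 4. PLS path modelling

Driver analysis uses partial least squares structural equation
modelling with reflective constructs (e.g. TEMP, PHYSIC, REDOX, TREE
explaining stem/soil flux constructs). `pls_sem()` implements the
classical iterative algorithm: standardized indicators, mode-A
(correlation) outer weights, path-scheme inner weighting (regression
weights toward predecessors, correlations toward successors), iterated
until the largest outer-weight change is below `tol` (default 1e-7;
non-convergence is an error that reports the last change, never a
silent result). Scores are unit-variance and sign-anchored to each
construct's first indicator, making estimates invariant to affine
rescaling of indicators. Centroid and factorial inner schemes are
provided for sensitivity analysis; path weighting is the default
because it is the default of the software ecosystem this workflow
mirrors.

**Composite vs consistent estimates.** Regressions among composite
scores are attenuated toward zero by measurement error — with three
indicators loading 0.8, path coefficients shrink by a factor of about
0.84. `method = "plsc"` applies the Dijkstra–Henseler correction:
the reliability $\rho_A$ estimated from the outer weights
disattenuates the construct correlation matrix before the structural
regressions, and loadings are rescaled accordingly. Simulation tests
use `plsc` when they compare estimates against generating parameters;
`method = "pls"` (the default) reproduces the classical composite
behaviour. Both coincide for single-indicator constructs, where the
model reduces exactly to OLS path analysis on standardized variables
— a reduction the test suite uses as an oracle.

**Assessment workflow.** `assess_measurement()` reports indicator
reliabilities with the conventional classification (eliminate below a
loading of 0.400, consider for removal in [0.400, 0.708], retain
above), Cronbach's alpha, composite reliability $\rho_C$,
Dijkstra–Henseler $\rho_A$, and AVE (criterion ≥ 0.50), plus the
HTMT discriminant-validity matrix with percentile bootstrap CIs
(default 10 000 subsamples, 90 % CI; criterion: upper bound < 0.90).
HTMT uses absolute inter-indicator correlations, the common
implementation convention. Elimination is advisory — flagged
indicators are surfaced for the analyst, not removed automatically,
because removal decisions in this workflow are substantive, not
mechanical. `assess_structural()` reports VIF from the latent score
correlations (flag above 5; exact collinearity is an estimator error
upstream), percentile bootstrap CIs for every path (default 10 000
subsamples, 95 %; "significant" means the CI excludes zero, failed
resamples counted), and R^2. `indirect_effect()` bootstraps the
product of coefficients along a chain — the product-CI construction is
one convention and is labelled as such. `predictive_rmse()` runs
k-fold cross-validation of indicator predictions through the
structural chain against a saturated linear regression on all
exogenous indicators with identical folds; `model_select_bic()` ranks
candidate structural models by $n\ln(\mathrm{SSE}/n) + k\ln n$ of the
target construct's regression, ties broken toward fewer parameters.
Missing indicator values are an error: imputation is out of scope and
silently dropping rows would bias every statistic downstream.

## 5. The synthetic-data generator

No raw field campaign is distributed, so every downstream stage is
validated against generated data with known ground truth.

`make_concentration_series()` inverts the flux equation exactly: the
noise-free slope, refit and converted, returns the generating flux to
machine precision — the round-trip identity every pipeline test rests
on. Noise is i.i.d. Gaussian on concentration, the simplest model
under which the OLS slope is the maximum-likelihood estimator;
sampling is 1 Hz for 300 s, matching a five-minute closure.

`simulate_campaign()` emulates the field design: sites with species
labels, five to six trees each, stem chambers at ordered height
intervals, four seasons with subtropical mean temperatures (17.5,
23.0, 28.9, 25.7 °C), and soil chambers alongside. True stem fluxes
are lognormal with a geometric height decay (default 0.5 per
interval, concentrating CH4 emission at the stem base) and a
configurable temperature effect on log-flux (default 0.05 per °C, a
moderate Q10-like forcing). `flux_presets()` carries species-level
magnitude presets anchored to reported mangrove means (e.g. the
*Avicennia marina* stem N2O mean of ~521 µg m^-2 h^-1); they are
labelled presets, not estimates. The truth table records both the
deterministic log-flux location and the realized flux for every
deployment, so recovery tests need no access to generator internals.
Within-tree replication per season is a free parameter
(`replicates_per_season`), since field designs differ on it.

What the generator does **not** emulate: tidal or diurnal dynamics,
spatial autocorrelation among trees, non-Gaussian analyzer noise,
chamber leakage or saturating-diffusion curvature, and negative trace
gas fluxes in the truth (lognormal magnitudes are positive; observed
negative fluxes still arise through noise and are handled
sign-faithfully). Passing tests therefore demonstrate the arithmetic
chain and estimator calibration under a clean generative model — not
robustness to the full pathology of field data.

`simulate_latent_model()` generates recursive latent systems with
unit-variance construct scores and reflective indicators
(`loading x latent + scaled noise`), validating positive
semi-definiteness of the implied covariance before simulating. It is
the ground truth for all PLS-SEM recovery and type-I error tests.

## 6. Problem sizes and numerical conventions

Test and validation runs use desk-scale sizes chosen to exercise the
asymptotics without waste: chain recovery at n = 2000 with a fixed
seed; 100-replicate parameter-recovery sweeps at n = 500; null-edge
type-I checks over 50 seeded replicates with 1000 bootstrap
subsamples; campaign identities on one site, two trees, two to four
intervals. Bootstrap defaults in the API remain at the
reporting-grade 10 000 subsamples.

Other conventions, collected: slope fitting requires ≥ 3 points and
strictly increasing times; R^2 is clamped to [0, 1] against round-off;
tiny negative structural error variances from floating point are
clamped to zero in the generator; geometry intervals must be ordered,
non-overlapping, positive-width; report tables round to 2 decimals
while all internal computation is full precision; all randomness in a
pipeline run flows from a single configured seed, and simulation
functions leave the caller's RNG state untouched.

## 7. Limitations

The package upscales seasonal means only — no gap-filling, no
temporal interpolation, no pneumatophore- or canopy-specific
pathways. The linear chamber model is the only one offered. PLS-SEM
supports reflective measurement only; formative modes and moderation
analysis are out of scope. Hypothesis tests comparing groups
(Kruskal–Wallis, Dunn, Wilcoxon) are deliberately not wrapped: base R
provides them, and the package adds nothing by re-exporting them.
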
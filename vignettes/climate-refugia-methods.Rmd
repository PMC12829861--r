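---
title: "Screening protected areas as climate refugia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protected areas as climate refugia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rare plants are losing climatically suitable habitat as temperatures rise.
A practical conservation question is which protected areas (PAs) will still
be suitable for a species decades from now — and, because many species cannot
disperse across a fragmented landscape, which *currently unoccupied* PAs
could receive assisted colonisations. `refugia` implements this screening as
a reusable pipeline:

1. **Suitability surfaces.** Each species has a gridded habitat-suitability
   score in [0, 1] for a baseline ("current") and a future period, at the
   10 km ("hectad") resolution used for British plant recording. The package
   does not fit these distribution models; it post-processes them.
2. **Habitat refinement.** A hectad keeps its score only if at least one fine
   land-cover cell inside it carries one of the species' preferred classes;
   otherwise the score is set to zero. Sub-cell presence of usable habitat is
   enough, because the species only needs *somewhere* in the hectad to live.
3. **Threshold.** The species' suitability threshold tau is the 10th
   percentile of refined current suitability at the cells where the species
   was actually recorded: any site at least as suitable as the bulk of the
   occupied range is treated as potentially manageable for the species.
4. **Zonal maxima.** For each PA and period, the maximum score over all cells
   whose footprint shares positive area with the PA polygon. Any-intersection
   (not cell-centre containment) is essential: most British PAs are far
   smaller than one hectad and centre-based rules would drop them.
5. **Classification.** Per (species, PA):
   occupied and future max ≥ tau → *in situ refugium*; occupied and future
   max < tau → *at risk*; unoccupied with both maxima ≥ tau → *ex situ
   refugium* (a candidate introduction site); otherwise none.
6. **Count models.** Species-per-PA refugia counts (separately for in situ
   and ex situ) are regressed on six standardised PA covariates with a
   spatially explicit Bayesian Poisson model.

## Classification conventions

*Occupancy overrides modelled current suitability.* An occupied PA is
classified on its future suitability alone. Occupancy is direct evidence of
current suitability, and this is the only reading under which
`occupied = at_risk + in_situ` holds exactly, as it does in the published
per-species tables this package reproduces in its worked example.

*Percentile convention.* tau uses linear interpolation between closest order
statistics (zero-based position $(n-1)p/100$; `stats::quantile()` type 7).
The convention is configurable; because every downstream comparison is
order-based, any strictly increasing rescaling of the scores (with tau
recomputed) leaves classifications unchanged — the test suite checks this
with a cubic map on a scenario whose occupied-cell count places the
percentile exactly on an order statistic.

*Thresholds are computed after habitat refinement* (the refined surface is
what the rest of the pipeline consumes) and the same tau is applied to both
periods. *Missing values* are excluded from percentiles and maxima; a PA
whose intersecting cells are all missing is excluded from classification for
that species, with a message.

## The spatial count model

For PA $i$ with covariate row $x_i$ and centroid $s_i$:

$$y_i \sim \mathrm{Poisson}(\exp(x_i^\top\beta + w(s_i)))$$

with a Gaussian-process random field $w$ with squared-exponential covariance
$k(d) = \sigma^2\exp(-d^2/(2\rho^2))$, realised as a low-rank predictive
process on $m$ knots placed by k-means over PA centroids
($w(s) = k(s, \mathcal{K})K(\mathcal{K},\mathcal{K})^{-1}w^*$,
$w^* \sim N(0, K)$). Defaults: $m = 15$ knots, Normal(0, 5²) priors on
coefficients, half-normal priors on $\sigma$ (scale 1) and $\rho$ (scale =
half the data extent). A Gaussian field is used rather than a heavier-tailed
one: it is simpler, and nothing in the screening outputs distinguishes them.

Inference is adaptive random-walk Metropolis-within-Gibbs, written in the
package. The field is sampled in non-centred (whitened) form
($w^* = \sigma U^\top u$, $u \sim N(0, I)$), which removes the funnel between
$\sigma$ and the field that stalls centred samplers when the field is weak;
an additional intercept/field recentring move breaks their confounding.
Proposal scales adapt only during warmup (target acceptance 0.3, clamped to
[1e-4, 5] so near-flat conditionals cannot run the scale away), so the
post-warmup kernel is a fixed Metropolis kernel and detailed balance holds.
Convergence is monitored with split-R-hat across ≥ 2 chains; any parameter
above 1.05 flags the whole fit non-converged (returned with a warning, never
silently). Significance follows the credible-interval rule: positive if the
95% interval lies above zero, negative if below, none otherwise.

Checks: with the field suppressed (prior scale 1e-6 on $\sigma$) posterior
means match an independent maximum-likelihood Poisson regression; on data
simulated from the model (n = 400 PAs, $\sigma = 0.3$) the 95% intervals
cover the true coefficients at close to nominal rate; the field evaluated at
a knot returns that knot's effect; a very long range collapses the field to
a constant.

## The synthetic study system

No British dataset ships with the package. `generate_scenario()` builds a
planar stand-in with the statistical structure the analysis assumes, so every
stage is testable end to end. "Latitude" and "longitude" are realised as
northing/easting in metres on a 600 km × 600 km domain of 10 km cells.

- **Elevation** (on a 1 km fine grid): a south-to-north ramp to 500 m plus a
  smooth random field (SD 200 m, 15 km bandwidth), plus fine-scale relief
  (amplitude up to 150 m) whose local strength is modulated by an independent
  smooth field — rugged lowlands and smooth upland plateaux both occur, so
  within-PA elevational range is not a mere proxy of mean elevation. Fields
  are built by smoothing seeded white noise with Gaussian kernels; clipped at
  sea level.
- **Land cover**: nearest-nucleus mosaic of 10 classes from 150 seeded
  nuclei (patches of a few tens of km); each species prefers up to three
  classes, the first being the commonest class near its climatic optimum.
- **Suitability**: inverse logit of a quadratic penalty on (a) planar
  distance to a species optimum and (b) the distance from the species'
  preferred elevation to the *span of elevations present in the cell* — a
  topographically varied hectad offers microclimates to species with many
  different preferences, the mechanism hypothesised to make rugged PAs
  disproportionately valuable. A per-(species, cell) residual (SD 0.6 on the
  logit, shared between periods) emulates the cell-scale heterogeneity of
  real SDM surfaces. The future surface shifts each optimum 150 km poleward
  and 170 m upslope, matching the field-standard equivalence of roughly
  145 km of latitude per 167 m of elevation per degree of warming.
- **Occupancy**: each cell with refined current suitability above 0.5 is
  recorded occupied independently with probability 0.1. The low rate reflects
  rare species whose realised occurrence set is far smaller than their
  climatic envelope; it is what makes most identified refugia unoccupied
  (ex situ), as in the real screening.
- **Protected areas**: 2500 axis-aligned rectangles (the real British estate
  has ~7000 NNRs/SSSIs), log-normal areas with median ≈ 1 km² and a long
  right tail, log-uniform aspect ratios in [0.1, 10] (many real reserves are
  elongated river, coast or verge features). All overlay code uses true
  geometric intersection, so real polygons drop in unchanged.

Every generator draws from a stream derived deterministically from one root
seed, so identical configurations reproduce bit-identical landscapes.

### What the synthetic system does and does not show

Passing tests on this system demonstrates that the pipeline's logic —
thresholding, overlay, classification accounting, covariate construction,
and the count-model inference — behaves correctly under known structure.
It does not validate the ecological realism of any particular SDM, and two
of its emergent regression patterns deserve honest caveats:

- The *ex situ share* of refugia comes out near 85% (the real screening
  reported 72%): occupancy sampling is independent per cell, while real
  records cluster with recorder effort.
- The partial effect of PA *area* on ex situ counts is structurally weak
  here. Larger PAs do intersect more cells (which raises their zonal maxima
  and in situ counts), but an independently occupied cell set penalises large
  PAs in the ex situ model (they are more often occupied and therefore
  excluded), and log-area and log-elevational-range are mechanically
  correlated for sub-kilometre PAs. In this synthetic world those forces
  leave the ex situ area coefficient near zero or mildly negative, and the
  in situ elevational-range coefficient positive but not always
  significant. The package reports whatever the fitted model finds; the
  direction pattern on mean elevation, latitude (ex situ), in situ area and
  habitat structure reproduces the hypothesised upland/poleward pattern.

## Numerical choices

- Polygon–cell overlay uses Sutherland–Hodgman clipping with a shoelace
  area; contact counts only above a relative tolerance of ~1e-14 of the cell
  area, so boundary touching never counts as intersection.
- Log transforms of mean elevation, elevational range and area use a fixed
  +1 offset (1 m, 1 m, 1 m²) so flat or sea-level PAs stay in the analysis;
  all six covariate columns are z-scored over the analysed set and the
  centring/scale constants are retained for back-transformation.
- The kernel matrix at the knots carries a 1e-8 diagonal jitter; a matrix
  still singular after jitter raises an error suggesting fewer knots.
- MCMC defaults (2 000 iterations, half warmup, ≥ 2 chains) suit the
  few-thousand-PA problem sizes used throughout the package's own experiments
  (classification on 2 500 PAs; recovery studies at n = 400 with 20
  replicates); all are configurable.

## Known limitations

- Rectangular synthetic PAs cannot probe concave-polygon edge cases, though
  the clipping code handles arbitrary simple polygons.
- The sampler is a random-walk scheme: adequate at these problem sizes, but
  not competitive with gradient-based samplers for many more than a few
  thousand observations.
- The pipeline treats the suitability surfaces as given; uncertainty in the
  underlying distribution models is not propagated.
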
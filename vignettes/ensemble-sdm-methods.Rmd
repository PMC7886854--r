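---
title: "Methods: ensemble niche modelling, pseudo-absence design and scenario projection in ensdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche modelling in ensdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ensdm)
```

# The model and its assumptions

`ensdm` estimates an Environmental Suitability Index (ESI ∈ [0, 1]) per
grid cell from presence-only occurrence records, then projects it under
climate scenarios. Three assumptions carry the whole construction:

* **Niche, not dispersal.** ESI expresses whether local environmental
  conditions are suitable; it says nothing about whether the species can
  reach a cell, persist through biotic interactions, or find substrate.
  Projected "range shifts" are shifts of *potential* habitat.
* **Presence-only data with heterogeneous effort.** Occurrence records
  from aggregated public databases oversample well-surveyed coasts. The
  environmental filtration step (one record per 0.5 °C × 0.5 bin of
  environmental space) deliberately discards geographic sampling density
  so that each *observed environmental condition* enters the model once.
* **Pseudo-absences are environmental, not geographic.** Absences are
  unobservable for mobile marine species; instead, environments outside a
  trimmed convex envelope of the presences are declared unsuitable-by-
  construction and used to calibrate the classifier members (NPPEN needs
  none).

# Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| grid resolution | 0.1 | degrees | resolution of the analysis grid all data are aggregated to |
| depth cutoff (cleaning) | 1000 | m | precautionary bound: the modelled shelf species are rarely observed deep, but bathymetric variation near narrow shelves argues against a tighter cut at cleaning time |
| filtration bin widths | 0.5 / 0.5 | °C / psu | resolution of the environmental filtration domain for thermal factors and salinity |
| hull quantile pairs | (2.5, 97.5), (5, 95), (10, 90) | percent | the three tested hull permeabilities; trimming is per dimension in raw factor units |
| pseudo-absence count | = filtered presences | — | class balance by design |
| collinearity screen | 0.7 | \|Pearson r\| | standard multicollinearity threshold over presence-cell values |
| CV design | 10 × 70/30 | — | repeated random stratified splits; 10 replicates make the calibration set representative of the filtered dataset |
| CBI validation threshold | 0.5 | CBI | members at or below it are discarded as not statistically validated |
| CBI windows | w = 0.1, 101 midpoints | suitability | standard continuous-Boyce convention (unspecified upstream; fixed here once) |
| hierarchical filter | 300 m, 50 km | m / km | commonly observed depth range; 50 km ≈ 5 cells covers suitable coastal cells without a shelf |
| RCP trends | 0.10 / 0.25 / 0.45 | °C per decade | synthetic bottom-warming presets, ordered RCP2.6 ≤ RCP4.5 ≤ RCP8.5 |

# What the synthetic world emulates — and what it does not

`generate_contemporary_stack()` builds a 60 × 40 cell shelf sea at 0.1°:
SBT decreasing poleward (24 → 8 °C) with per-cell noise, a seasonal
amplitude (hence SBTrange) increasing eastward, SSS increasing eastward,
a shelf deepening offshore with a break to > 1000 m (so the cleaning
cutoff and the 300 m filter both bite), and a southern land strip giving
a coastline for the distance-to-coast filter. Monthly SBT series are
generated and the thermal indices *derived* from them, so the index
definitions are exercised, not bypassed.

The true niche is Gaussian and separable per factor,
`s(x) = s_max · exp(−Σ (x_f − μ_f)² / 2σ_f²)` with defaults
μ = (16 °C, 5 °C), σ = (2.5, 2), s_max = 0.9 — the simplest structure the
SDMs can recover, which keeps parameter-recovery tests well-posed.
Occurrences are Poisson-thinned from intensity ∝ suitability × sampling
bias over ocean cells; the expected total is `n_target` scaled by the
best achievable suitability relative to `s_max`, so a niche whose optimum
is not realised on the grid yields few records (both stated behaviours —
"~n_target for a matched niche" and "thinning for a mismatched one" —
cannot hold under plain normalisation; this is the resolution we chose).
Dates are uniform over 1990–2017 (the pooled contemporary period).

Scenario fields are `contemporary + bias + trend × decades-since-baseline`
per GCM, with the per-cell bias field frozen across decades of one GCM.
What a green test therefore establishes: the *procedure* (filtration,
hull design, NPPEN, CBI selection, delta correction, centroid tracking)
behaves as specified on data with the right statistical shape. What it
does not establish: skill on real occurrence databases (taxonomic error,
spatial autocorrelation, coastline-following effort), real CMIP5 fields
(spatially structured, seasonally varying bias; circulation change), or
multi-species results.

# Numerical choices

* **NPPEN.** Reference distances are computed against the full-sample
  mean/covariance (a leave-one-out variant sits behind
  `leave_one_out = TRUE`); this is the simplest formulation consistent
  with the counting definition and is exactly testable against a
  brute-force oracle. The covariance is ridged with
  `eps = 1e-6 · trace(V)/d` (doubled until the condition number drops
  below 1e8), so duplicated columns degrade gracefully instead of
  failing.
* **Point-in-hull.** Membership is a phase-1 simplex feasibility test
  (Bland's rule; exact LP in any dimension) with tolerance 1e-9 in factor
  units; boundary points count as *inside* and are therefore excluded
  from pseudo-absence sampling — "outside" is strict. In 2-D the hull is
  pre-reduced to its vertices; in 1-D it degenerates to the trimmed
  interval.
* **Filtration ties.** The keeper within an occupied bin is the first
  record in cell-id order — deterministic and permutation-invariant.
* **CBI degenerate cases.** Windows with zero background mass are
  dropped; if the surviving P/E sequence is constant the rank correlation
  is undefined and reported as 0 (no ranking information). All-windows-
  dropped is an error, not a silent 0.
* **Curve screening.** Curves are smoothed with a centred 5-point moving
  average (edge-padded) before peak counting; plateaus are collapsed
  before sign-change detection so flat tops are not double-counted.
* **Selection tie-breaks.** Among configurations tied on mean CBI
  (rounded at 1e-10): fewer factors first, then the wider hull quantile
  (10–90 before 5–95 before 2.5–97.5) — matching the observed preference
  for permeable hulls with widely distributed species.
* **Delta correction.** Applied per factor (SBT family alike); SSS is
  restored from the observation baseline (kept constant in time), as are
  the static bathymetry and distance fields.

# Open design points and how we resolved them

* **CBI background**: all ocean cells of the calibration domain (standard
  Boyce usage), not the pseudo-absence set. A consequence: the a-posteriori
  distance-to-coast flag cannot influence the selection statistic, so it
  is ensemble metadata applied by `hierarchical_filter()`, not a candidate
  axis.
* **Quantile trimming** is per dimension in raw factor units — the
  simplest reading of "outer quantiles", and the one consistent with bins
  stated in raw units.
* **Importance metric**: 1 − mean Pearson r between the reference ESI map
  and maps with one factor permuted across ocean cells (n = 10
  permutations), computed on the ensemble (or a probe NPPEN during the
  collinearity screen).
* **Decade ESI** is predicted once from decade-mean corrected fields
  rather than averaging yearly predictions (desk-scale economy; the
  yearly route would require yearly scenario fields the generator does
  not pretend to resolve).
* **Ensemble mean is unweighted** across members × CV replicates; no CBI
  weighting is applied anywhere.

# Known limitations

* Only GLM, GAM and an in-package single-hidden-layer ANN are available
  as classifier members in this installation; GBM, FDA, MARS and RF ids
  are recognised but error informatively. NPPEN is always available.
* Layer stacks serialise to long-format CSV (with a metadata header)
  rather than NetCDF/GeoTIFF — no NetCDF reader exists in the target
  environment. The containers and contracts are format-agnostic.
* The simplex membership test is exact but O(LP) per point; pools are
  environmentally deduplicated first, which keeps it in the hundreds of
  calls per selection.
* Coordinates are treated as planar for cell assignment and centroids
  (cells, not areas; a `cos(lat)` area weighting is available behind a
  flag). At basin scale and 0.1° this is the conventional choice.
* The lat/lon inversion heuristic (`swap_check`) is off by default: no
  stated rule exists, and a heuristic that silently reclassifies data is
  worse than a flagged one.
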
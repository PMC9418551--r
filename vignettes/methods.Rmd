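---
title: "Methods: the light-use-efficiency model behind efitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the light-use-efficiency model behind efitr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efitr)
```

## The model and its assumptions

`efitr` estimates the theoretical maximum total net primary productivity
of a forest site (tNpp_tmax, Mg ha⁻¹ yr⁻¹) as the product of the solar
energy available during the growing season and a chain of efficiencies,
then scores the field observation against it: eFit = 100 ·
tNpp_obs / tNpp_tmax.

The chain is deliberately minimal. It is *not* a full Farquhar–von
Caemmerer–Berry model: there is no J_max/V_cmax distinction, no light
response curve, and — by construction — no water or nutrient
limitation. The only environmental inputs are monthly mean temperature,
monthly mean daily solar radiation, and the annual mean atmospheric CO₂
of the observation year. The model's assumptions are:

* photorespiration is a constant fraction of photosynthesis, captured by
  the CO₂ compensation point Γ\* and the rubisco-limited term W_i;
* PAR is a fixed 45% of total shortwave radiation;
* a closed canopy absorbs 90% of incoming PAR during active growth;
* intercellular CO₂ is a fixed 0.7 of atmospheric CO₂;
* the temperature entering Γ\* is the growing-season mean G_t, not the
  annual mean — months that cannot support growth do not set the
  operating temperature of photosynthesis.

Under these assumptions tNpp_tmax is an upper reference: eFit near 100%
means the stand converts close to everything its radiation and
temperature climate permits; low eFit points to local constraints
(water, nutrients, stand structure, disturbance) that the model
excludes on purpose.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `gas_const_R` | 0.008314 | kJ mol⁻¹ K⁻¹ | molar gas constant in the Arrhenius term |
| `arrh_c` | 19.02 | – | Arrhenius scaling constant for Γ\* |
| `arrh_dHa` | 37.83 | kJ mol⁻¹ | activation energy for Γ\* |
| `ci_ratio` | 0.70 | – | c_i / c_a for C3 canopies |
| `beta` | 0.45 | – | fraction of absorbed quanta reaching PSII |
| `alpha_leaf` | 0.90 | – | leaf absorptance |
| `eps_i` | 0.90 | – | canopy PAR interception efficiency |
| `par_frac` | 0.45 | – | PAR fraction of total solar radiation |
| `spec_energy_K` | 18.2 | MJ kg⁻¹ | specific energy of plant dry biomass |

At the defaults, Γ\*(25 °C) ≈ 42.9 µmol mol⁻¹, within 1% of the standard
published C3 value (≈ 42.75); the test suite asserts the closed form and
documents the literature anchor. `alpha_leaf` and `eps_i` are kept as
two parameters even though both default to 0.90: one is a leaf optical
property entering ε_c, the other a canopy-level interception term
entering the energy budget, and a user may legitimately change either
alone.

Two literature values circulate for the specific energy of dry biomass,
18.2 and 18.4 MJ kg⁻¹. The package defaults to 18.2 (the value used by
the model's source parameterization in two of its three statements);
18.4 is one `lue_params(spec_energy_K = 18.4)` away.

## The growing season

A month belongs to the growing season iff its mean temperature is
**at or above** 0 °C. Descriptions of this family of models sometimes
say "exceeds zero" (strict); the executable formulation they ship sets
only sub-zero months to missing, which retains exactly-zero months. We
follow the executable rule and expose both the threshold
(`warm_threshold`) and strictness (`strict`) as arguments, so either
reading is available.

* G_d sums the calendar days of included months on a fixed non-leap
  calendar (Jan 31, Feb 28, …), so G_d ∈ [0, 365].
* G_t and G_srad are *unweighted* means over included months — a row
  mean over monthly columns, not a day-weighted mean. Day-weighting
  would change G_srad by under a percent for realistic climates but
  would depart from the model's defining formulation.
* Missingness propagates, never imputes: a month with missing
  temperature is excluded outright; a warm month with missing radiation
  still counts toward G_d but drops out of the G_srad mean, and the
  season is flagged incomplete.
* An empty season is a valid result: G_d = 0, G_t and G_srad undefined
  (`NA`, never 0), tNpp_tmax = 0 and eFit undefined.

## Units in the productivity formula

The canonical formula multiplies the per-day radiation mean by the
season length:

```
E [MJ m⁻² yr⁻¹] = G_srad · G_d · par_frac · eps_i · eps_c / 1000
tNpp_tmax [Mg ha⁻¹ yr⁻¹] = E / spec_energy_K · 10
```

Dimensional analysis forces the *division* by K (MJ m⁻² ÷ MJ kg⁻¹ →
kg m⁻²); the 1/1000 is kJ→MJ and the ×10 is kg m⁻² → Mg ha⁻¹. A compact
published variant of the formula (G_srad · ε_c · ε_i · K, no day count,
no PAR fraction, ε_i applied a second time) is not dimensionally
consistent with Mg ha⁻¹ yr⁻¹; it is exposed as
`tnpp_tmax(..., formula = "equation")` strictly for comparison and is
never used by `evaluate_site()`.

Negative net uptake (c_i ≤ Γ\*, reachable only at extreme cold or very
low CO₂) is clamped: tNpp_tmax = 0 with an `a_nonpositive` flag rather
than negative biomass. eFit > 100% is allowed but flagged — an
observation above the theoretical maximum indicates input or assumption
problems, not super-maximal growth.

## Rasters and buffered extraction

Climate can come from a per-site table or from 12 + 12 single-band
georeferenced rasters. The package reads **ESRI ASCII grids** (.asc), a
plain-text georeferenced format interchangeable with GeoTIFF via any GIS
tool; the package deliberately avoids a compiled GIS dependency.
Rasters are taken to be in geographic coordinates (lon/lat, WGS84);
reprojection is out of scope.

Point extraction returns the value of the cell containing the site.
With `buffer_m`, the extraction is the unweighted mean of all valid
(non-NoData) cells whose *centers* lie within great-circle (haversine)
distance `buffer_m` of the site. Because an azimuthal-equidistant
projection centred on the site preserves distances from that site, this
is exactly the circular metric buffer one would construct in such a
projection — without needing a projection library. Cell inclusion by
center is simple and deterministic; no area weighting is attempted.
NoData cells are excluded from the mean; a site whose every month is
unextractable (outside the extent) is flagged and carries an all-missing
climate rather than failing the run.

## Clustering: exact tiny instances, BUILD+SWAP beyond

Site structure is validated with partitioning around medoids (PAM) on
Euclidean dissimilarities (features z-scored by default, since typical
feature sets mix °C, kJ m⁻² day⁻¹ and days), with the number of clusters
chosen by maximum average silhouette width,
s(i) = (b(i) − a(i)) / max(a(i), b(i)).

`pam_cluster()` solves instances with `choose(n, k)` ≤ 5000 candidate
medoid sets *exactly* by enumeration, and uses the classic BUILD + SWAP
heuristic above that. The reason is empirical and worth recording: the
single-swap neighborhood of PAM has true local optima even at n = 7,
k = 2 — instances exist where no medoid/non-medoid exchange improves the
cost yet a better medoid pair exists, and the canonical reference
implementation returns the same suboptimal pair. Exhaustive enumeration
is cheap precisely in the regime where users can check it, so the
package is exact there by construction and heuristic (cost
non-increasing, deterministic, lowest-index tie-breaks) where
enumeration is infeasible. The heuristic path remains under test against
the exact path.

Singleton clusters get silhouette 0 (the usual convention). Ties in
silhouette-based selection break toward smaller k.

## The synthetic-data generator

`make_climate()` builds monthly series as a cosine annual cycle with a
July peak (T_m = mean + amplitude · cos(2π(m−7)/12), radiation
analogous) plus optional seeded Gaussian jitter. The July-peak
(northern) convention is harmless because only the *set* of warm months
matters downstream. `make_dataset()` emits a site table, a climate
table and a truth table computed by an independent straight-line
transcription of the model chain; observations are drawn as
fraction · tNpp_tmax · (1 + N(0, noise_sd)).

Default zone templates (boreal mean −2 °C amplitude 15; temperate 10/10;
tropical 26/1; radiation 9000–17000 kJ m⁻² day⁻¹) are chosen once as
caricatures of the three biomes the method targets, with observation
fractions 0.25–0.35 — forests typically realize a modest fraction of
their theoretical ceiling — and 10% relative observation noise. What the
generator emulates: multi-zone structure, the analytic growing-season
answer, CO₂-year coupling, deterministic seeding (per-site sub-streams,
so subsetting does not change draws). What it does not: real spatial
covariance of climate, actual biome geography, measurement error
structure of field NPP, disturbance history. A green round-trip test
therefore establishes the *pipeline's* correctness (I/O, season, model
chain, units), not the model's ecological adequacy.

## Numerical policy and limitations

All computation is double precision; outputs are serialized with full
precision and undefined eFit as an empty field plus a flag (never 0 or
textual NaN). Exact-year CO₂ lookup only — no interpolation; a fallback
concentration is applied solely when the caller supplies one. The
packaged Mauna Loa annual-means table (1959–2022) is a convenience
transcription of the public record; quantitative tests rely on synthetic
CO₂ tables, not on it.

Known limitations: no daily phenology or growing-degree-day model; no
southern-hemisphere month reindexing (unnecessary, as the warm-month set
is order-free); no raster reprojection; the clustering module stops at
PAM + silhouette (random-forest importance and t-SNE visualization are
intentionally out of scope and can be fed from this package's outputs).
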
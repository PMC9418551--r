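# efitr

Theoretical maximum forest productivity and Ecosystem Fit from monthly
climate.

## The problem

Field-measured total net primary productivity (tNpp, the sum of above-
and below-ground dry-biomass production, Mg ha⁻¹ yr⁻¹) tells you how much
a forest grew, but not how much it *could* have grown on that site. Two
stands with the same tNpp may sit at very different fractions of their
site's productive capacity, so raw tNpp is a poor basis for comparing
management effects or climate vulnerability across sites.

`efitr` computes a site-specific reference, the **theoretical maximum
potential total NPP** (tNpp_tmax): the biomass a closed C3 canopy would
produce from the solar radiation available during the growing season if
nothing but temperature, radiation and atmospheric CO₂ limited growth
(no water or nutrient limitation). The **Ecosystem Fit** index then
expresses realized capacity:

```
eFit = 100 · tNpp_obs / tNpp_tmax        [%]
```

It is aimed at forest ecologists and managers comparing plots across
climatic zones.

## The model

From monthly mean temperature and monthly mean daily solar radiation
(e.g. WorldClim-style normals extracted at the plot coordinates):

1. **Growing season** — months with mean temperature ≥ 0 °C contribute
   their calendar days to G_d; G_t and G_srad are the unweighted means of
   temperature and radiation over those months.
2. **CO₂ compensation point** (Arrhenius/Bernacchi form, at T = G_t):
   Γ\* = exp(19.02 − 37.83 / (R·(G_t + 273.15))), R = 0.008314 kJ mol⁻¹ K⁻¹.
3. **Intercellular CO₂**: c_i = 0.7 · c_a, with c_a the annual mean
   atmospheric CO₂ (ppm) for the observation year (Mauna Loa record
   packaged).
4. **Rubisco-limited uptake**: W_i = c_i / (4.5·c_i + 10.5·Γ\*),
   A = (1 − Γ\*/c_i) · W_i.
5. **Conversion efficiency**: ε_c = A · β · α with β = 0.45 (quanta to
   PSII) and α = 0.90 (leaf absorptance).
6. **Maximum productivity**: usable energy
   E = G_srad · G_d · 0.45 · ε_i · ε_c / 1000 (MJ m⁻² yr⁻¹; PAR fraction
   0.45, canopy interception ε_i = 0.90), converted to biomass by the
   specific energy of dry plant matter K = 18.2 MJ kg⁻¹ and to field
   units: tNpp_tmax = E / K · 10 (Mg ha⁻¹ yr⁻¹).

All constants are overridable through `lue_params()`.

## Worked example

```r
library(efitr)

# a cool-temperate plot: monthly normals, Jan..Dec
mc <- monthly_climate(
  temp = c(-8, -6, -1, 5, 12, 17, 19, 18, 13, 7, 0, -5),          # degC
  srad = c(3000, 5500, 9000, 13500, 17500, 19500,
           19000, 16500, 12000, 7500, 4000, 2500))                 # kJ/m2/day

derive_growing_season(mc)
#> Growing season: 244 days over 8 month(s); G_t = 11.38 degC,
#> G_srad = 13688 kJ/m^2/day

evaluate_site(list(site_id = "plot-17", year = 2005, tnpp_obs = 9.8), mc)
#>   site_id g_days g_temp  g_srad    c_a     c_i gamma_star       w_i
#> 1 plot-17    244 11.375 13687.5 379.98 265.986   20.65352 0.1881357
#>       a_net      eps_c tnpp_tmax     efit flags
#> 1 0.1735271 0.07027849     52.23 18.76316
```

Reading: eight months clear 0 °C (Apr–Nov, 244 days). At the
growing-season mean of 11.4 °C the compensation point is ~20.7 µmol
mol⁻¹; with 2005's CO₂ (380 ppm) the conversion efficiency is ~7.0%, and
the site could at most produce ~52.2 Mg ha⁻¹ yr⁻¹ of dry biomass. The
observed 9.8 Mg ha⁻¹ yr⁻¹ realizes 18.8% of that capacity (eFit).

Batch use: `read_sites()` + `read_climate_table()` or
`extract_monthly()` (ESRI ASCII raster stacks, optional metric buffer) →
`evaluate_sites()` → `groupwise_r2()` and PAM clustering
(`dissimilarity_matrix()`, `pam_cluster()`, `select_k()`). Synthetic
datasets with analytic truth tables come from `zone_template()` /
`synth_spec()` / `make_dataset()`. A command-line front end is exposed as
`efit_cli()` (subcommands `compute`, `synth`, `cluster`, `params`; see
`inst/scripts/efit`).

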
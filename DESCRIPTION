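Package: efitr
Title: Ecosystem Fit and Theoretical Maximum Forest Productivity from a
    Light-Use-Efficiency Model
Version: 0.1.0
Authors@R: person("efitr", "maintainers", email = "efitr@example.org",
    role = c("aut", "cre"))
Description: Computes a forest site's theoretical maximum potential total net
    primary productivity (tNpp_tmax) from monthly climate normals and annual
    atmospheric CO2 using a simple light-use-efficiency model (growing-season
    radiation, canopy interception efficiency, and a temperature- and
    CO2-dependent photosynthetic conversion efficiency built on the CO2
    compensation point), and the Ecosystem Fit index
    eFit = 100 * tNpp_obs / tNpp_tmax.  Includes readers for site tables,
    monthly climate tables and georeferenced ASCII raster stacks with
    buffered extraction, a growing-season derivation from monthly normals,
    partitioning-around-medoids clustering with silhouette-based selection of
    the number of clusters, group-wise correlation summaries, and a fully
    seeded synthetic-data generator with analytic truth tables for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
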
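Package: palmerdrift
Title: Surface Residence Time and Connectivity of a Coastal Biological
    Hotspot from Gridded Surface Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lagrangian analysis of hourly gridded ocean surface-current
    maps (such as those produced by coastal high-frequency radar networks)
    over a canyon-associated biological hotspot.  Provides passive-particle
    advection with fourth-order Runge-Kutta integration, e-folding surface
    residence time for a footprint and its sub-regions, sub-region
    connectivity, least-squares tidal harmonic analysis and de-tiding,
    merging and windowed averaging of station winds, model-II (major-axis)
    regression of residence time on wind speed, and a seeded generator of
    synthetic radar-like velocity fields and station winds so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
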
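Package: rivercarb
Title: Riverine Organic Carbon Loads and Inter-Station Watershed Yields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates mean riverine particulate and dissolved organic carbon
    loads at gauging stations from paired streamflow/concentration
    observations using the nine LOADEST rating-curve regression models with
    AIC selection and bias-corrected retransformation; traces hydrologic-unit
    (HUC12/ToHUC style) drainage networks to accumulate station drainage
    areas; levels stations by river-network connectivity and allocates net
    carbon yield (gain or loss) to the incremental watershed between nested
    stations by mass balance; and provides the two internal validation
    procedures (derived-vs-reported drainage areas, inversed-load
    consistency). A synthetic-watershed generator produces catchment trees,
    station placements, flow and concentration records, and ground-truth
    yield fields with known mass-balanced station loads, so every stage can
    be exercised against exact answers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
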
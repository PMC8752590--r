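Package: ecoclimex
Title: Ecoclimatic Index Modelling for Pest Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semi-mechanistic ecoclimatic niche model for gridded pest risk
    analysis, in the CLIMEX tradition. Converts monthly climatologies to weekly
    series, computes weekly temperature and moisture growth indices on a
    soil-moisture bucket model, accumulates cold, heat, dry and wet stress,
    gates persistence on an annual degree-day requirement, and combines them
    into the 0-100 Ecoclimatic Index (EI). Includes irrigation scenario
    analysis, suitability classification with latitude-weighted area
    accounting, host-overlap accounting, occurrence-based performance
    statistics, one-at-a-time parameter sensitivity and sampled-parameter
    uncertainty maps, plus a synthetic-data module generating archetypal
    climate grids, irrigation masks and occurrence sets so the full pipeline
    runs without external downloads. Ships a fall armyworm (Spodoptera
    frugiperda) parameter profile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'risk-analysis.R'
    'params.R'
    'engine.R'
    'sensitivity.R'
    'scenarios.R'
    'cli.R'
    'grid-io.R'
    'climate-io.R'
    'synthetic-data.R'
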
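Package: geopheno
Title: Mobility Phenotypes from Smartphone Location Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preprocesses raw smartphone location traces into context-enriched
    movement data by detecting stationary episodes (stay points), merging
    recurrent visits to the same real-world place with density-based
    clustering on a haversine metric, and inferring the home location from
    dominant nighttime dwell. From the context-enriched data it derives
    per-day and per-window behavioral phenotypes used in digital
    phenotyping of neuropsychiatric populations: places visited, unique
    places visited, trajectories, home stay, normalized location entropy,
    and diurnal movement regularity. Includes evaluation metrics
    (episode-level stay-point accuracy, place-clustering accuracy, Adjusted
    Rand Index with epsilon tuning), a deterministic synthetic trace
    simulator that emits ground-truth labels for validation, and an
    end-to-end pipeline with CSV/GeoJSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    geosphere,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
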
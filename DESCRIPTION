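Package: eooassess
Title: Extent-of-Occurrence Estimation and Red List Screening from
    Multi-Source Occurrence Records
Version: 0.1.0
Authors@R:
    person("EOO", "Assess Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the extent of occurrence (EOO) of species from
    georeferenced occurrence records as the geodesic area of the minimum
    convex polygon, assigns hypothetical IUCN Red List categories under
    strict criterion-B1 area thresholds, and compares assessments derived
    from literature records, aggregator (GBIF-style) records, and their
    combination. Includes Darwin-Core-style CSV ingestion with an ingest
    report, out-of-region flagging, category-by-source summary tables, a
    seeded synthetic occurrence generator with known true ranges for
    end-to-end validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
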
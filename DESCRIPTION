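Package: telclean
Title: Compilation and Rule-Based Filtering of Passive Acoustic Telemetry
    Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing detection data from passive acoustic telemetry
    receiver arrays. Compiles heterogeneous raw receiver export files into one
    canonical detection table, attributes receiver-deployment, station and
    animal metadata by interval joins, and removes spurious detections with two
    configurable rules: a solitary-detection rule (detections with no
    same-animal neighbour within a chosen delay) and an iterative
    speed-feasibility rule based on station-to-station distances, receiver
    detection ranges and per-animal maximum swimming speeds. Includes a
    Haversine distance-matrix builder, an exporter to the file layout used by
    downstream telemetry analysis packages, and a seeded synthetic-data
    generator with ground-truth labels for end-to-end validation. Every stage
    partitions its input exhaustively, so no detection is silently lost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    lubridate,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
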
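Package: prelever
Title: Pose-Track Behavioral Metrics for Cocaine Self-Administration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of pose-estimation trajectories from rodent
    operant cocaine self-administration experiments. Reads per-frame keypoint
    coordinate tables, repairs missing detections, calibrates pixels to
    centimeters, and aligns recordings to lever extension; derives locomotion,
    nose motion, lever-zone entrances, entrances per meter traveled, and
    occupancy heatmaps; computes pre-lever incentive-salience composite
    z-scores with a High/Low median split, psychomotor sensitization and
    tolerance labels from noncontingent drug sessions, and categorical
    abstinence codes; encodes the session timeline, dosing, progressive-ratio,
    and footshock schedule arithmetic; and ships a correlated-random-walk
    session simulator so the full pipeline is testable with planted,
    recoverable effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
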
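Package: motorcall
Title: High-Throughput Classification of Larval Zebrafish Motor Behavior
        from Keypoint Pose Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Turns multi-well-plate keypoint pose tracks of larval zebrafish
        (8 midline key points per frame, 160 frames per second) into classified
        motor calls: stationary, scoot, routine turn (R-turn),
        acoustic-startle-like (AsLB) and visual-startle-like (VsLB) behavior.
        Pose tracks are cut into overlapping 40-frame windows, egocentrically
        aligned, normalized and flattened into feature vectors; a semi-supervised
        pipeline (KMeans clip mining, PCA at 95 percent retained variance, random
        forests per plate format) assigns per-window calls, which majority voting
        smooths into a per-frame ethogram. Downstream tools segment call runs
        into swim bouts, attach kinematics (speed, heading change, tail angle),
        and quantify stimulus-response rates for tap and dark-flash assays.
        Includes a synthetic keypoint-trajectory simulator so the whole pipeline
        is trainable and testable without external recordings, plus NetCDF/CSV
        readers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    ncdf4,
    randomForest,
    uwot
Suggests: testthat (>= 3.0.0), withr, cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
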
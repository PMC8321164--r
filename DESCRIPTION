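Package: hygiene2stage
Title: Two-Stage Multi-View Hand-Hygiene Action Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognises standard-level hand-hygiene actions in untrimmed
    two-view video (a third-person "wall" camera and an egocentric "chest"
    camera). A low-complexity 32x32 coarse CNN with motion-history-image
    fusion localises the hand-hygiene period; refinement classifiers then
    label seven hygiene actions (faucet with elbow or hand, rubbing with or
    without water, soap, drying, non-hygiene) only inside the candidate
    regions, verify a 20-second rubbing requirement and assemble a hygiene
    report. Includes a compact fully vectorised CNN engine, a seeded
    synthetic two-view session generator with frame-level ground truth,
    unit-based (1-second) evaluation with Jaccard index, duration error and
    existence accuracy, hand-crafted dry-hands baselines (HSV histogram,
    HOG, LBP with a random forest), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    Rcpp,
    jsonlite,
    png,
    randomForest,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
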
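Package: senphys
Title: Quantification of Sensorimotor Physiology in a Whisker-Based Go/NoGo Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed sensorimotor physiology
    experiments combining whole-cell electrophysiology, fiber photometry,
    pupillometry, and Go/NoGo behavior. Provides evoked-PSP amplitude and
    latency extraction with iterative decay subtraction, paired-pulse and
    train depression ratios, intrinsic action-potential features from
    current steps, isosbestic motion/bleach correction with robust (median
    absolute deviation) z-scoring of photometry traces, ellipse-based pupil
    area estimation with blink interpolation, signal-detection behavioral
    metrics (d-prime, bias) with expert-phase classification, trial-aligned
    windowing, sliding-window auROC statistics, and ground-truthed synthetic
    session generators for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
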
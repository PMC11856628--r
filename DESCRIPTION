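Package: ArthroScore
Title: Objective Quantification of Intra-Articular Bleeding in Arthroscopic Video
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Frame-wise colour-threshold scoring of arthroscopic surgical video.
    Blood pixels are classified by a calibratable predicate over HSV and CIELAB
    colour coordinates with frame-adaptive saturation and a* cut-offs, and the
    blood-pixel ratio inside the circular optical field is mapped to a 1-10
    bleeding score. Each second is scored from three randomly sampled frames and
    an abrupt-jump resampling rule suppresses transient red-tissue artifacts
    such as floating clot fragments. Whole recordings are summarised by a
    length-independent total bleeding score with optional surgical-phase means.
    The package also provides a synthetic arthroscopy frame generator with
    ground-truth scores, threshold calibration by coarse-grid search and
    coordinate descent, an RGB-only baseline scorer for ablation comparisons,
    and ANOVA-based intraclass correlation statistics (absolute agreement,
    single and mean-of-k units) with mean-absolute-error and score-subgroup
    reporting for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ArthroScore-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'colorspaces.R'
    'frame-io.R'
    'scoring.R'
    'threshold-spec.R'
    'synthetic.R'
    'calibration.R'
    'agreement.R'
    'report.R'
    'cli.R'
    'utils.R'
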
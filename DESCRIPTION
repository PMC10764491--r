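Package: swvmap
Title: Volumetric Mapping and Regional Statistics of Muscle Shear Wave Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional shear wave velocity (SWV) maps of
    skeletal muscle from pose-tracked 2D elastography frames, maps them into a
    standardized anatomical (slice, angular, radial) cell representation, and
    provides the associated reliability and regional-statistics layer:
    ICC(2,1) with F-based confidence intervals, standard error of measurement,
    inter-regional and inter-subject reliability summaries, paired pre/post
    contrasts and regional rank-correlation association with covariates. A
    built-in synthetic phantom and freehand scan simulator make every stage
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
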
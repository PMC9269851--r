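Package: gaitsym
Title: Whole-Body Gait Symmetry from a Single Trunk Accelerometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a correlation-based whole-body gait Symmetry Index (SI)
    from raw triaxial lumbar acceleration recorded during straight-line
    walking. The pipeline low-pass filters the sensor signal, removes the
    static gravity component by tilt correction, rotates acceleration into
    the earth frame, detects initial contacts, segments and time-normalizes
    left and right gait cycles, and maps the Pearson correlation between the
    side-mean anterior-posterior waveforms onto a 0-100 symmetry scale.
    Includes a synthetic gait-signal and cohort generator with known ground
    truth, anthropometry-based walking-speed normalization, and the
    cohort-level statistical battery: split-plot ANOVA with
    Greenhouse-Geisser correction, Bonferroni pairwise comparisons, and
    canonical linear discriminant analysis with Wilks' lambda and structure
    matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
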
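Package: mtmpose
Title: Quantifying Infant Movements Toward the Midline from 2D Pose Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify infant movements toward the body midline (MTM)
    from markerless 2D pose-estimation output. Reads 33-landmark pose time
    series, computes midbody-line signed limb distances and limb-enclosed
    areas normalized by body length, scores annotated MTM events into
    occurrence percentages and per-minute rates, and runs the associated
    correlation and group-comparison analysis (Spearman with Fisher-z
    confidence intervals, t and Mann-Whitney U tests). Includes a seeded
    synthetic supine-infant landmark generator with ground-truth midline
    contact events so the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
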
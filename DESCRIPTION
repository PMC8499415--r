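Package: gingrec
Title: Automated Curvature-Based Measurement of Gingival Recession
Version: 0.1.0
Authors@R: person("gingrec", "developers", role = c("aut", "cre"),
    email = "gingrec@example.org")
Description: Measures gingival recession depth on bucco-oral cross-sections of
    dental 3D surface scans. Reads triangle meshes (STL), extracts planar
    cross-sections in a per-tooth local frame, fits an arc-length
    parameterised cubic spline, computes signed curvature at 0.01 mm
    resolution ("curvature combs"), detects the cemento-enamel junction and
    gingival margin as concave-curvature extrema at convex-to-concave
    transitions, and measures the inter-landmark distance. Includes the
    matching observer-agreement analysis (arc-length deviation of manual
    picks, Bland-Altman limits of agreement, intraclass correlation,
    curvature-threshold stratification) and a synthetic arc-chain profile
    generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
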
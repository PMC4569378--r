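Package: handmorph
Title: Surface Registration and Average Shape Models for 3D Hand Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the reproducibility of 3D surface scans of
    the human hand and for building statistical average hand models. Provides
    rigid iterative-closest-point (ICP) surface registration with exact
    point-to-surface distance maps and their percentile summaries, groupwise
    rigid Procrustes registration of anatomical landmark sets, a per-subregion
    (palm + five digits) adapted ICP registration that absorbs finger
    articulation between captures, average landmark configurations with
    per-landmark covariance ellipsoids, thin-plate-spline average surfaces,
    paired comparison of registration methods, and signed distance maps
    between group-average shapes. A parametric articulated synthetic hand
    generator with ground-truth landmarks and region labels supports
    end-to-end testing and simulation of repeat acquisitions and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
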
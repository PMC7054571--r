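Package: hgseg
Title: Automated Surface-Based Segmentation of Heschl's Gyrus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Refines an atlas-based parcellation of auditory cortex into a
    fine delineation of Heschl's gyrus (the first transverse temporal gyrus)
    on the cortical surface. Reads and writes FreeSurfer on-disk formats
    (binary triangle surfaces, per-vertex curvature and thickness, Destrieux
    style annotations, ASCII labels), provides vertex-graph morphological
    operators (erosion, dilation, opening), discrete curvature estimators,
    constrained region growing, and anatomical quantification (grey matter
    volume, surface area, thickness, curvature and folding indices) of the
    resulting label. Includes a deterministic generator of synthetic
    supratemporal-plane surface patches (single gyrus, common stem
    duplication and full posterior duplication morphotypes, with injectable
    atlas labelling errors) so the full pipeline can be exercised without
    MRI data, plus the small statistical toolkit used to validate automated
    against manual volumes (Pearson, partial and dependent correlation
    comparisons, paired tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
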
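Package: seedphenom
Title: High-Throughput Seed and Seedling Phenotyping from 3D Tomograms and
    Time-Lapse Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis toolchain for automated seed and seedling
    phenotyping of sugar beet (Beta vulgaris). Segments X-ray
    microtomography scans of dry seeds into embryo, perisperm, seed coat
    and internal cavity by marker-controlled watershed, and derives
    per-compartment morphometry (volume, surface area, 3D shape factor,
    equivalent spherical diameter, filling factor). Detects germination
    events in time-lapse image series by seed movement and radicle
    protrusion and computes germination kinetics (mean germination time,
    T50/T70, early and final germination rates) at multiple temperatures.
    Measures radicle and shoot elongation of heterotrophically growing
    seedlings from green-channel time-lapse imagery, aligned to each
    seed's own germination hour. Ships synthetic-data generators with
    exact voxel-level ground truth so every stage of the chain can be
    validated without access to scanner or camera hardware, and
    assembles results into a 28-variable, crop-ontology-coded phenotype
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    withr,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
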
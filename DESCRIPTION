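Package: chromoscene
Title: Headless Visualization Pipelines for 3D Genome Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A columnar data model for 3D genome structures (chromatin models
    inferred from Hi-C or simulated de novo), with genomic-range and spatial
    (cutting-plane, spherical-neighborhood) filtering, a declarative
    grammar-of-graphics view configuration resolved to concrete per-bin visual
    attributes (mark, color, scale, links), aggregation of BED/GTF interval
    annotations into structure bins, and export of resolved scenes to colored
    PLY/OBJ meshes and static PNG previews. Includes a confined random-walk
    simulator that generates structures and annotations with planted spatial
    signal for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    png,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
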
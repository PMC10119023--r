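Package: cambiokit
Title: Polar Projection and Stem-Cell Fate Analysis of Cambial Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative analysis of radial organ cross-sections around the
    vascular cambium. Provides a polar image-projection pipeline (rotation to
    the primary xylem axis, centre-to-edge ray sampling, alignment of every
    angular column to the most recent periclinal division wall, cross-sample
    aggregation), the positional quantification rules used for cambial marker
    gradients (gradient reach, stem-cell marker spread, EdU overlap classes,
    xylem/phloem cell-type counts, control normalisation, chi-square
    comparison of categorical position tables), lineage-sector analysis of
    clonally marked cell files, and a stochastic simulator of bifacial
    stem-cell fate decisions under gibberellin regimes. A synthetic-data
    generator emulates annotated cell files and renderable section images with
    ground truth attached, so the whole pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
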
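Package: synmorph
Title: 3D Synaptic Morphometry from Labeled FIB/SEM-Like Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional synaptic morphometry of the kind
    performed on focused ion beam/scanning electron microscopy (FIB/SEM)
    reconstructions of cortical neuropil. Generates seeded synthetic labeled
    volumes with known ground truth (dendritic shafts, spines, synaptic
    junctions), extracts the synaptic apposition surface (SAS) of each
    junction as a triangulated mesh, computes its area, perimeter and
    curvature with tissue-shrinkage correction, classifies junctions by type
    (asymmetric vs symmetric), shape (macular, perforated, horseshoe-shaped,
    fragmented) and postsynaptic target (spine head or neck, aspiny or spiny
    dendritic shaft), counts objects inside an unbiased three-dimensional
    counting frame, and compares groups with omnibus and partitioned
    chi-square contingency statistics plus nonparametric size comparisons.
    Bundles published reference count tables from a 3D electron microscopy
    study of human transentorhinal cortex layer II for a table-reproduction
    mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
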
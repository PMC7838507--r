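Package: bitvox
Title: Bit-Plane-Separated Multiresolution Volume Format and Progressive
    Streaming for Teravoxel Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a bit-plane-separated, multiresolution chunked volume
    format for large 3D grayscale microscopy images, together with the tools
    around it: a pyramid planner, a lossless bit-plane codec, a reformatter
    that converts raw volumes into an on-disk tree of LZW-compressed TIFF
    bitBlocks, a static HTTP store and fetcher, a progressive
    volume-of-interest loader that refines images one bit-plane at a time,
    2D projection and annotation utilities (maximum intensity projections,
    orthogonal slices, point/line/contour annotations with SWC export), and
    a deterministic fluorescence-like phantom generator for self-contained
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    curl,
    tibble,
    dplyr,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
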
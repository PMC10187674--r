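Package: xlinkplot
Title: Comparative Visualization of CLIP Crosslink Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-command comparative visualization of nucleotide-resolution
    CLIP (crosslinking and immunoprecipitation) crosslink tracks. Reads
    crosslink positions from BED or signed BedGraph files, auxiliary interval
    tracks from BED/BED9, orthogonal coverage from bigWig and a reference GTF
    annotation; applies library-size (crosslinks-per-million), maximum-peak or
    custom normalization and rolling-mean or Gaussian-kernel smoothing; and
    composes a publication-quality multi-panel figure (crosslink, auxiliary,
    coverage and annotation tracks) for a genomic region of interest given by
    gene name, gene id or coordinates. A deterministic synthetic fixture
    generator emits toy datasets in every consumed format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    zoo,
    ggplot2,
    patchwork,
    optparse
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
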
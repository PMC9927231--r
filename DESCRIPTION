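Package: plastotyper
Title: Comparative Plastome Analysis and Cytotype Heteroplasmy Quantification
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genomes segregating
    as two cytotypes within a species. Reads GenBank flat files and per-site
    base-count profiles, detects the quadripartite LSC/IRa/SSC/IRb plastome
    architecture, calls normalized SNPs and indels between assemblies by
    unique-anchor chaining with affine-gap realignment, detects inversions,
    annotates coding effects, scans microsatellites with MISA semantics,
    computes sliding-window nucleotide diversity and neighbor-joining trees,
    and quantifies low-frequency heteroplasmy from quality- and
    strand-filtered base counts at cytotype-diagnostic loci, with a
    depth-ratio guard against nuclear and mitochondrial plastid-DNA inserts.
    Includes a seeded synthetic-data generator emulating a two-cytotype,
    mixed-frequency deep-sequencing design so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
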
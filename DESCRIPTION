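Package: tilescan
Title: High-Density CRISPR Gene-Body Tiling Scan Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled CRISPR dropout screens built on high-density
    gene-body tiling libraries. Enumerates saturating NGG-anchored sgRNA
    libraries over a coding sequence, extracts and counts protospacers from
    raw screen reads via vector-backbone anchors, converts guide frequencies
    to control-anchored normalized CRISPR scores (negative-control median 0,
    positive-control median -1), smooths guide scores onto protein residue
    coordinates by Gaussian kernel regression, calls CRISPR-hypersensitive
    elements and cell-line-selective essential domains, projects per-residue
    scores onto structure models (Chimera attribute files and PDB B-factors),
    ranks genes in TSS-targeting screens by a permutation test against
    negative-control guides, and simulates complete dropout screens
    (Dirichlet-multinomial counts and backbone-structured FASTQ reads) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
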
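Package: hdacpcm
Title: Proteochemometric Modeling of HDAC Inhibitor Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteochemometric (PCM) regression of inhibitor activity across
    a panel of histone deacetylase (HDAC) isoforms.  Builds multi-block
    descriptor matrices (protein sequence-similarity, structure-similarity
    and backbone-geometry blocks; physical-property and topological ligand
    blocks), forms protein-ligand cross-terms, fits epsilon-insensitive
    support vector regression under the Pearson VII universal kernel, and
    validates models with PRESS-based Q-squared statistics.  A downstream
    selectivity screen classifies compounds as pan, class-selective or
    isoform-selective inhibitors from their predicted affinity profiles.
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline can be exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    kernlab,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
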
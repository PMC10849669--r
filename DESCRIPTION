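Package: msigkit
Title: Mutational Signature Refitting, Spectra Statistics and UPGMA Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline toolkit for single-base-substitution (SBS96) mutational
    catalogs: reading and writing catalog, signature and exposure tables;
    non-negative least-squares (Lawson-Hanson) refitting of reference
    signatures with per-sample residual (r-norm) diagnostics; cosine
    similarity and pairwise cosine-distance matrices; UPGMA agglomerative
    clustering with annotated trees, double clustering of exposure matrices
    and Newick export; per-sample summary, two-sample spectra comparison and
    grouped log-count boxplot statistics; and a synthetic catalog simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'schema.R'
    'similarity.R'
    'catalog.R'
    'refit.R'
    'clustering.R'
    'io.R'
    'simulate.R'
    'cli.R'
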
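Package: mcam
Title: Multiple Clustering Analysis for Quantitative Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ensemble ("multiple") clustering analysis of quantitative
    peptide-by-condition matrices, such as phosphotyrosine time courses.
    Expands a combinatorial grid of row-wise transforms, distance metrics,
    clustering algorithms and cluster numbers into an ensemble of partitions;
    scores every cluster of every partition for overrepresentation of
    categorical biological and dynamic labels with hypergeometric tests under
    per-family Benjamini-Hochberg false discovery rate control; prunes
    clustering parameters whose removal improves ensemble-wide enrichment; and
    mines the surviving ensemble through pairwise mutual information,
    parameter-quartile analysis, peptide co-occurrence matrices, robust
    label-driven clusters and cross-dataset co-occurrence comparison. Includes
    a synthetic-data generator with planted temporal groups and annotation
    structure, plus matrix- and label-randomization controls with empirical
    false-positive-rate evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    class,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
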
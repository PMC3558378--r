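Package: perfectphylo
Title: Perfect Phylogenies for Three-State Characters via Minimal
    Separators
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides and constructs perfect phylogenies for matrices of
    taxa described by discrete characters with at most three states.
    The pipeline works on the partition intersection graph: legal
    minimal separators are generated from proper clusters of the
    matrix, a maximal pairwise parallel family is saturated into a
    proper minimal triangulation, and a clique tree built by Maximum
    Cardinality Search is read out as the phylogeny.  Includes matrix
    readers and writers (CSV/TSV and a PHYLIP-like digit dialect),
    Newick output, synthetic generators for tree-derived matrices and
    worst-case caterpillar families, exhaustive brute-force oracles for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
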
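Package: sisterclade
Title: Sister-Clade Extraction from Collections of Gene Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: High-throughput screening of gene phylogenies for the nearest
    neighbours of a clade of interest. Given newick gene trees whose leaf
    labels carry group identifiers (e.g. taxonomic phyla), the package
    locates a target clade without assuming a meaningful root (monophyly is
    decided on the unrooted bipartition set), extracts the up-to-two
    alternative sister subtrees implied by the two possible rootings
    together with the branch support for each association, summarises
    sisters through a user-supplied nested hierarchy of group classes, and
    aggregates results across thousands of trees into parseable
    tab-separated reports. Includes a synthetic gene-tree generator with
    planted sister scenarios for validation, and a command-line driver for
    pipeline use. Typical applications include screening phylomes for
    candidate horizontal gene transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
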
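Package: cladetrim
Title: Taxonomy-Aware Dereplication of Large Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("cladetrim", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Reduces the OTU (operational taxonomic unit) density of large
    phylogenetic trees without sacrificing taxonomic diversity. Internal
    nodes whose statistical support meets a user threshold are screened for
    taxonomic homogeneity against a reference table of OTU lineages; the
    most inclusive single-category clades are then collapsed down to a
    user-chosen number of representatives whose root-to-leaf path lengths
    best match the clade median. Includes a Newick reader/writer that
    preserves support values across common dialects, a synthetic tree
    generator with planted clades for testing, a brute-force reference
    implementation, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
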
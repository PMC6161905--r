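Package: rfbound
Title: Exact Worst-Case Bounds and Normalization for Robinson-Foulds
    Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Robinson-Foulds-type distances between phylogenetic trees
    (the tree partition distance for unrooted trees, the cluster distance
    for rooted trees, and the unrooted cluster distance across the
    rooted/unrooted divide) together with the exact strict worst-case
    bound for each fixed pair of tree topologies.  The bound equals the
    number of internal edges in both trees minus the number of degree-2
    internal nodes in both trees, and a constructive algorithm produces
    leaf labelings that attain it, so normalized distances can be
    computed exactly instead of by randomized approximation.  Includes
    multifurcating Newick input/output, degree-2 node suppression,
    topology generation and exhaustive enumeration for small leaf
    counts, and a brute-force oracle over all labelings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
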
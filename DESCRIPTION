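Package: treeloops
Title: Exact Counting of Non-Isomorphic Trees with Self-Loops
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic-programming counters for the number of mutually
    non-isomorphic rooted and unrooted trees with a given number of
    vertices and self-loops (no multi-edges), using exact
    arbitrary-precision integer arithmetic throughout.  Unrooted counts
    are obtained from the rooted table through the unicentroid/bicentroid
    decomposition, and from them exact lower and upper bounds on the
    number of tree-like polymer topologies of a given cycle rank.  A
    brute-force enumerator provides independent ground truth on small
    instances, and a command-line front end exposes the counters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
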
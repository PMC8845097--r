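Package: chronobounds
Title: Extreme Divergence-Time Bounds for Phylogenies Under Rate Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, for every node of a rooted phylogeny with molecular
    branch lengths, the youngest and oldest divergence times consistent with
    a user-supplied interval of conceivable substitution rates and optional
    minimum/maximum node-age calibrations. The feasible age intervals are
    obtained by exact interval-constraint propagation over the tree (one
    postorder and one preorder pass) and are returned both as a per-node
    bounds table and as the two extreme chronograms that realise every
    youngest (respectively oldest) age simultaneously. Includes a heuristic
    for deriving a deliberately wide rate interval from the variation of
    terminal sister-branch lengths, an independent shortest-path verification
    oracle based on difference constraints, and a simulator of Yule trees
    with an optional clade-specific speciation-rate increase, lognormal
    branch rates, and finite-site substitution-count noise, used to run
    coverage experiments for the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
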
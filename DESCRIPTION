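Package: knotscan
Title: Probabilistic Knot and Slipknot Detection in Open Polygonal Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects knots and slipknots in open polygonal chains such as
    protein alpha-carbon backbones. Open chains (or any of their subchains)
    are closed stochastically through vertices of a randomly rotated
    truncated icosahedron on a large enclosing sphere, simplified with the
    KMT triangle-elimination algorithm, and classified by exact integer
    evaluations of the Alexander polynomial, with HOMFLY-based chirality
    calls. All-subchain scans yield knotting-fingerprint matrices from
    which knot cores, tails, slipknot loops and a compact topological
    notation (e.g. K4_1_3_1, S3_1) are derived. Includes readers for PDB
    and plain x-y-z coordinate files, a parametric fixture generator for
    knotted and slipknotted test curves, and a command-line interface for
    single structures and trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
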
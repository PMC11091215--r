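Package: fuchsine
Title: Exact Degree-Based Topological Indices of Supramolecular Fuchsine Sheets
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs the supramolecular Fuchsine sheet graph F[m,n] by
    pendant-vertex fusion of 40-vertex dye units and computes its degree-based
    topological indices (Zagreb family, forgotten, harmonic, atom-bond
    connectivity, geometric-arithmetic, general Randic) exactly, using
    arithmetic in the surd ring Q + Q*sqrt(2) + Q*sqrt(3) + Q*sqrt(6).
    Derives closed-form bilinear expressions in the sheet dimensions from the
    edge partition, cross-checks them against direct edge summation and a
    numeric bilinear fit, and audits published closed forms and comparison
    tables for this graph family, flagging every cell or coefficient that
    disagrees with direct computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
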
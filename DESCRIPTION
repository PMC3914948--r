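Package: rss3d
Title: RNA Secondary Structure Derived from 3D Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives RNA secondary structures from three-dimensional
    atomic coordinates (mmCIF or PDB). Base pairs (canonical and
    non-canonical) and base stacks are detected by geometric criteria
    from standard base reference frames; helices are assembled as
    continuous base-paired stacks faithful to strand connectivity;
    pairs are classified as secondary or tertiary; helices are
    classified as nested or non-nested with pseudoknot layering via
    exact maximum-weight crossing-free selection; base triples are
    decomposed into pairs of base pairs; results are serialized to CT,
    extended BPSEQ, layered dot-bracket and lossless JSON, with rRNA
    domain partitioning support. Ships a generator for idealized A-form
    coordinate fixtures and pairing-list topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
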
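Package: quadtet
Title: Identification and Classification of Tetrads and Quadruplexes in
    Nucleic Acid Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tetrads (planar 4-cycles of base-paired nucleotides)
    and quadruplexes (stacks of tetrads) in nucleic acid 3D structures read
    from PDB or mmCIF files, or from pre-computed base-pair annotations in
    DSSR-style JSON.  Each tetrad is assigned one of the six ONZ topology
    classes (O+, O-, N+, N-, Z+, Z-) from the 5'-to-3' arrangement of its
    residues, and each quadruplex an ONZM class combining the tetrad letter
    (or M for mixed), the parallel/antiparallel/hybrid strand progression,
    and a +/-/* subtype.  For multimeric motifs an exhaustive chain
    reordering maximises the number of O-class tetrads.  Output includes a
    two-line dot-bracket encoding of the quadruplex secondary structure,
    plain-text and JSON reports, and deterministic arc-diagram graphics in
    SVG.  A synthetic fixture generator produces annotation graphs and
    rigid-geometry coordinate models with known ground-truth classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
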
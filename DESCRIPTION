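Package: atomtrail
Title: Carbon Atom-Mapping Models for Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and checking carbon atom-mapping models of
    metabolic networks, the input required by 13C metabolic flux analysis.
    Reads and writes MDL MOL/RXN (V2000) files with atom-atom map numbers,
    assigns a deterministic, isomorphism-invariant canonical atom ordering
    to metabolite structures, computes symmetry orbits, validates reaction
    carbon balance and mapping integrity, resolves per-reaction mappings
    from a local identifier-indexed mapping store, assembles network-wide
    ABC-format models from a simple 4-column CSV network description, and
    traces labeled carbon positions through the resulting model, including
    deliberate single-error injection to demonstrate how one wrong atom
    mapping propagates through a pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
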
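Package: sketchmol
Title: Headless Primitives for 2D Molecular Diagram Sketching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless molecular-diagram sketching engine. Publication-quality
    2D connection tables are built by replaying short scripts of discrete
    editing primitives (subject -> action -> result), with no pointing device:
    atom and bond property edits, geometry-template perception and new-bond
    angle inference, congestion scoring, template grafting with guide atoms,
    sketch equivalence testing, and MDL molfile/SD input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
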
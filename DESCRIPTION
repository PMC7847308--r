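Package: gietr
Title: Graphene-Induced Energy Transfer as an Axial Ruler for
    Membrane-Bound Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes distance-dependent fluorescence quenching of dipole
    emitters above graphene-coated substrates from first principles
    (plane-wave expansion of dipole emission near stratified media),
    turns the resulting lifetime/intensity-ratio curves into an axial
    ruler with nanometer precision, calibrates DNA-nanoruler tilt by
    global least squares, and analyses single-molecule intensity traces
    into conformational states and transition kinetics via change-point
    segmentation and hidden Markov modelling. Includes synthetic-data
    generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
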
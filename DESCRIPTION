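Package: hemepocket
Title: Structure-Function Analysis of Heme-Binding Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the relationship between the tertiary
    structure of heme-binding sites and the function of their host
    proteins.  The package extracts heme sites from PDBx/mmCIF structure
    files with occupancy/altloc resolution and completeness, axial-ligand,
    coverage and sequence-redundancy filters; assigns function labels
    (oxygen binding, oxidoreductase, dual function, electron transport)
    from EC numbers, GO terms, keywords and descriptions via a fixed rule
    cascade; voxelizes the protein environment into four-channel binary
    occupancy grids in a heme-centric coordinate frame; trains and
    cross-validates a 3D convolutional neural network classifier;
    localizes predictive information by outside/inside occlusion sweeps;
    and quantifies cavity-shape variability of protein groups through
    binary cavity vectors and their mean distance from the group
    barycenter.  A synthetic-site generator produces labelled
    porphyrin-plus-pocket structures so the whole pipeline can be
    exercised without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
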
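Package: profun
Title: Protein Function Prediction from Structure with a Hierarchical
    Graph Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-label Gene Ontology (GO) term prediction from protein
    3D structure. Residue-level graphs are built from C-alpha contact maps
    and one-hot (optionally language-model) residue features, encoded with
    graph convolutions, and pooled through a hierarchical attention module
    in which learnable super-nodes summarise functional substructure.
    Training combines binary cross-entropy with an InfoNCE contrastive
    regulariser over perturbed graph views. Includes CAFA-style evaluation
    (protein-centric Fmax, Smin, function-centric AUPR), gradient-weighted
    class-activation (grad-CAM) residue saliency, GO ontology handling with
    information content, and a synthetic planted-motif structure generator
    so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
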
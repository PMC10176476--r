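Package: afmid
Title: Molecular Identification from High-Resolution AFM Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies quasiplanar organic molecules from stacks of ten
    constant-height high-resolution atomic force microscopy (HR-AFM) images by
    casting identification as image captioning: a first multimodal recurrent
    network predicts the set of chemical moieties (attributes) present, and a
    second, attribute-conditioned multimodal recurrent network generates the
    full IUPAC name term by term. Ships an IUPAC term tokenizer with dataset
    admission filters, a constrained nomenclature grammar and physics-inspired
    AFM stack simulator for fully synthetic training data, two-stage teacher
    forced training with operational-parameter and image-deformation
    augmentation, and BLEU n-gram evaluation with a term-level error taxonomy
    and embedding-space neighbor analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
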
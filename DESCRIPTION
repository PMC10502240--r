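Package: epifusion
Title: Multimodal Prediction of Epigenetic Profiles from DNA Sequence and
    Chromatin 3D Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts binary epigenetic event profiles (transcription-factor
    binding, DNase hypersensitivity, histone marks) for 1-kb genomic windows
    by fusing a local convolutional (or convolutional-recurrent) DNA sequence
    encoder with a global chromatin-structure encoder (multilayer perceptron
    or graph convolutional network) built on whole-genome Hi-C interaction
    frequency matrices. Includes a rank-sum disparity test quantifying when
    chromatin interaction frequency explains disagreement between sequence
    similarity and epigenetic profile similarity, first-layer-kernel to
    position-specific frequency matrix motif extraction with MEME export,
    zero- and few-shot noncoding variant effect scoring (including a Siamese
    reference-versus-alternate classifier and chromosome-grouped eQTL
    cross-validation), and a synthetic-data generator that plants sequence
    motifs and contact-map community structure so the whole pipeline is
    testable at desk scale without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
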
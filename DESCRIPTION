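Package: cytodistill
Title: Knowledge Distillation with Multi-Exit Self-Distilling Networks for
    Single-Cell Cytology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training library for cervical single-cell image classification by
    teacher-student knowledge distillation fused with a multi-exit,
    self-distilling student network. The student is a staged convolutional
    backbone with a classifier exit after every stage; each exit branch carries
    a global-context attention block and a bottleneck that unifies feature
    scales, the deepest exit supervises the shallow ones through
    temperature-softened soft labels and a feature mean-squared penalty, and
    inference averages the softmax outputs of all exits. Includes a seeded
    synthetic cell-image generator emulating a five-class dataset whose classes
    differ by nucleus size, nucleo-cytoplasmic ratio, boundary irregularity and
    texture, stratified 3:1:1 dataset splitting, the standard augmentation
    pipeline, the two-stage transfer-then-distill training procedure, and
    confusion-matrix / macro-metric reporting with ensemble inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    caret,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
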
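Package: supcam
Title: Chromosome Cluster Type Identification by Supervised Contrastive
    Pretraining with Category-Variant Image Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for identifying chromosome cluster types (instance,
    touching, overlapping, touching-overlapping) in karyotyping images via a
    two-step pipeline: supervised contrastive pretraining with a labeled
    momentum memory queue, augmented by category-variant image composition
    with label look-up tables and a self-margin angular contrastive loss,
    followed by fine-tuning of a linear classification head and
    macro-averaged multiclass evaluation.  Includes a synthetic generator of
    banded, curved chromosome-like cluster images so the whole pipeline is
    testable without the clinical dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
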
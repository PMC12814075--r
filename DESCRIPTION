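Package: gliomaconn
Title: Functional Connectivity and Network Topology of Multifocal Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a macroscale analysis of glioma
    natural progression from resting-state fMRI, built around multifocal
    gliomas whose paired lesions (larger = later stage) act as a natural
    within-subject progression contrast. Provides a synthetic-cohort
    simulator with known tumor-cortex coupling; BOLD preprocessing and
    motion/variance/tSNR quality control; voxel-wise ALFF, fALFF and
    regional homogeneity; tumor-seeded functional connectivity against a
    cortical parcellation with contralateral mirror controls; tumor-as-node
    brain-graph topology across a sparsity sweep with small-world
    validation; a normality-gated paired testing workflow with
    dual-criterion positivity, Bonferroni families and mixed-effects
    confounder adjustment; and a sequential gene-upregulation filter for
    staged differential-expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    lme4,
    jsonlite,
    RNifti,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
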
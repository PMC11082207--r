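Package: revscreen
Title: Ligand-Based Reverse Screening for Small-Molecule Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the most probable protein targets of bioactive small
    molecules by ligand-based reverse screening. A query compound is compared
    to the known actives of every candidate target using two orthogonal
    similarity measures, a Manhattan-based similarity of ElectroShape 5D
    (ES5D) conformer descriptors and the Tanimoto coefficient of path-based
    1024-bit fingerprints, and the two scores are combined into a probability
    by size-stratified binary logistic models (one model per heavy-atom
    class, coefficients smoothed across classes by a cubic polynomial).
    Includes the curation and validation methodology around the engine:
    bioactivity filtering and activity labelling, structure standardization,
    training-pair construction with alleged inactives, 10-fold
    cross-validation with Matthews correlation, success-at-rank evaluation
    with knowledge and scaffold-diversity stratification, Bemis-Murcko and
    Oprea scaffold analysis, Z-factor comparison of physicochemical spaces,
    and a seeded synthetic bioactivity universe generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: OpenBabel command line tool (obabel) on the PATH
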
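Package: smfpls
Title: Fragment-Based QSPR Modelling of Ionophore Sensitivity by Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-property relationship (QSPR) modelling of the
    potentiometric sensitivity (mV per decade) of plasticized-membrane
    ion-selective electrodes from the chemical structure of their ionophores.
    Molecules given as SMILES are converted to hydrogen-suppressed Kekule graphs
    and described by substructure molecular fragment counts: every shortest
    atom/bond path of 2 to 9 atoms, written as a canonical alternating
    atom/bond string. Fragment count matrices are related to sensitivity with
    NIPALS PLS1 regression, the number of latent variables is chosen by
    leave-one-out cross-validation, and descriptors are pruned by a threshold on
    the weighted regression coefficients before a final refit. Includes signed
    fragment-importance reporting, prediction for new ionophores with an
    applicability-coverage warning, a seeded generator of random valence-legal
    small molecules carrying a planted fragment-additive property for
    simulation studies, and JSON model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
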
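Package: BacteroidFBA
Title: Constraint-Based Modeling of Nitrogen-Fixing Bacteroid Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of core metabolic models of
    nitrogen-fixing rhizobial bacteroids. Provides S4 containers for
    stoichiometric models with elemental formulas and gene-protein-reaction
    (GPR) rules, network consistency checks (elemental balance, orphan and
    dead-end detection, stoichiometrically balanced cycles), flux balance
    analysis with taxicab-norm (L1) minimization, loopless flux variability
    analysis, shadow prices, phenotype phase planes, single-gene deletion,
    random-objective ensemble FBA, and exact enumeration of elementary
    conversion modes (ECMs) by double description of the conversion cone.
    Includes a fully specified synthetic core-bacteroid model generator
    (dicarboxylate catabolism, TCA cycle, electron transport, nitrogenase,
    GS-GOGAT, alanine dehydrogenase, storage polymer synthesis) together
    with bacteroid-specific conversion metrics (oxygen demand per carbon,
    oxygen per dinitrogen fixed, carbon cost per nitrogen) and biological
    filters, plus scenario orchestration for carbon-source comparison,
    glutamate-demand forcing and essentiality benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    MASS,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
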
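Package: cramertree
Title: Cramer Classification Trees with Decision Traces and Concordance
    Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An auditable rule engine for the Cramer classification scheme
    used in threshold of toxicological concern (TTC) assessment. Implements
    the original 33-question decision tree, its five-rule extension, and the
    revised decision tree with in silico hydrolysis/reduction of esters,
    acetals and disulphides, all defined as editable JSON rule graphs over
    SMARTS predicates, look-up lists and computed structural conditions.
    Every classification returns a complete decision trace that can be
    replayed and compared across schemes to locate the rule at which two
    classifications diverge. Companion statistics quantify inter-source
    agreement (classification concordance, weighted and unweighted Cohen
    kappa with confidence intervals, per-class TPR/TNR/PPV, intra-class
    concordance) and locate structural drivers of disagreement through
    SMARTS-fingerprint chi-square enrichment over discordance pools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, DecisionTree, Classification
RoxygenNote: 7.3.3
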
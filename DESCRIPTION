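Package: stabQTL
Title: Stability QTL Mapping for Multi-Environment Trials Under Contrasting
    Nitrogen Nutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits and of their stability across environments in multi-environment
    trials run under contrasting nitrogen fertilization. Provides simulation
    of doubled-haploid and diversity-panel genotypes on a genetic map with
    multi-trial phenotypes of known variance structure; marker quality
    control, identity-by-state kinship, pairwise linkage disequilibrium and
    Sved-curve LD-decay fitting; variance-component estimation (expected
    mean squares and EM-REML) with broad-sense heritabilities for
    multi-environment, per-trial and single-environment designs; Wricke
    ecovalence over nitrogen levels or trials as a mappable stability trait;
    kinship-based mixed-model association scans with FDR control and
    LD-derived confidence intervals; composite interval mapping for
    doubled-haploid populations; projection of QTL onto a common map;
    classification of loci as stable or interaction-driven; and
    environment characterization by principal components and hierarchical
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
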
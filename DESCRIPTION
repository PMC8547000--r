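Package: saltrare
Title: Rare and Abundant Bacterial Community Analysis Along Salinity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for partitioning soil bacterial communities into rare,
    intermediate and abundant taxa and contrasting their ecology along an
    environmental (salinity) gradient: taxonomic and phylogenetic alpha and
    beta diversity with label-shuffle null models (SES.MNTD, betaMNTD),
    community assembly partitioning via betaNTI and Bray-Curtis Raup-Crick
    null models, phylogenetic signal of environmental preferences
    (Blomberg's K, Fritz-Purvis D), threshold indicator taxon analysis
    (change points, purity/reliability, environmental breadth), an ecosystem
    multifunctionality index with a functional-redundancy surrogate, and a
    seedable synthetic-data generator so that every stage can be exercised
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
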
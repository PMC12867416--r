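Package: guildnet
Title: Microbial Guild Dynamics from Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how groups of co-occurring gut microbes ("guilds")
    reorganize between health and disease states. Builds signed OTU co-occurrence
    networks from centered log-ratio transformed count tables (Spearman association
    with Benjamini-Hochberg FDR control), extracts the cross-condition stable
    network, partitions it into guilds with modularity-based community detection
    and Zi-Pi topology scores, tests sub-network topology against node-subset
    permutation null models, quantifies attack robustness of the largest connected
    component, stratifies samples into clear and "grey zone" states from classifier
    probabilities, and pools guild-abundance odds ratios across cohorts with
    fixed-effect meta-analysis. Includes a seeded logistic-normal multinomial
    simulator that plants correlated guild blocks, group abundance shifts with a
    target odds ratio, and transitional mixture samples, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
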
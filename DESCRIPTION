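Package: tdssnet
Title: Time-Delayed S-System Gene Regulatory Network Inference by Hybrid
    Gene Expression Programming
Version: 0.1.0
Authors@R: person("tdssnet", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers instantaneous and time-delayed gene regulatory networks
    from multi-replicate time-series expression data. Each target gene is
    fitted independently with a time-delayed S-system (TDSS) model whose
    structure, kinetic parameters and integer delays are co-evolved by a
    hybrid of restricted gene expression programming and a genetic
    algorithm, executed under a partition-based map/reduce-style generation
    loop. Includes a spec-matched synthetic benchmark generator (scale-free
    topologies, delayed edges, replicate time series), delay-aware
    sensitivity/specificity evaluation, file formats (expression TSV, edge
    TSV/SIF) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
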
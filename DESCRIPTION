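Package: pggsel
Title: Multilevel Selection Simulations of Public Goods Games with
    Voluntary Participation and Altruistic Punishment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of cultural group selection in public
    goods games with altruistic punishment and an optional nonparticipant
    (loner) strategy.  Implements the five-stage period update (erroneous
    contribution, punishment, payoff-biased imitation with between-group
    mixing, probabilistic group conflict with cultural takeover, and
    mutation), reproducible run orchestration with derived replicate
    seeds, and an experiment harness that sweeps the nonparticipant
    payoff and the group size to quantify the joint effect of voluntary
    participation and group selection on long-run cooperation.  Results
    are written as tidy CSV tables with JSON metadata sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
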
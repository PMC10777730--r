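Package: aprshield
Title: Aggregation-Prone Region Shielding Analysis for Coarse-Grained
    Protein-Excipient Systems
Version: 0.1.0
Authors@R:
    person("APRShield", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A post-simulation analysis pipeline for screening formulation
    excipients by their ability to shield aggregation-prone regions (APRs)
    of a protein. Detects APRs from sequence by sliding-window averaging of
    a per-residue aggregation-propensity scale, computes total and
    APR-restricted solvent-accessible surface area (SASA) of coarse-grained
    bead models and trajectories with a Shrake-Rupley dot algorithm,
    compares excipient systems against an excipient-free control with a
    Bartlett-gated Kruskal-Wallis/Welch ANOVA procedure and Dunn post-hoc
    tests, and fits a partial-least-squares structure-property model with
    leave-one-out component selection, repeated-split median Q2 validation
    and variable-importance-in-projection scores. A synthetic-data module
    generates surrogate trajectories and descriptor-response tables so the
    whole pipeline can be exercised without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
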
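Package: copolex
Title: Copolymer Surfactant Excipient Design and Screening
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for the rational design of amphiphilic
    copolymer excipients that stabilize protein formulations. Simulates
    per-chain copolymer compositions under the terminal (Mayo-Lewis) model
    with Schulz-Zimm chain-length dispersity, computes the compositional
    dispersity index (CDI) of the resulting per-chain composition scatter,
    extracts T10 aggregation-onset times from turbidity traces and
    equilibration rate constants from dynamic surface-tension traces, fits
    the three-regime molecular-weight structure-function models, and applies
    the a-priori design screen (low CDI, fast surface equilibration).
    Includes seeded synthetic-data generators for every input and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
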
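Package: coopcost
Title: Optimal Cost of Institutional Incentives for Cooperation in Finite Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the expected total cost of institutional reward and
    punishment for promoting cooperation in finite well-mixed populations
    evolving under the Fermi pairwise-comparison rule in the small-mutation
    limit. The cost is obtained exactly from the fundamental matrix of the
    absorbing birth-death Markov chain over cooperator counts, for the
    Donation game and the Public Goods game. Provides closed-form asymptotic
    limits (large population, weak and strong selection), the
    phase-transition threshold in selection intensity at which the cost
    ceases to be monotone in the per-capita incentive, and a decision
    procedure for the cost-minimal incentive that still guarantees a desired
    long-run cooperation frequency. A seeded Monte Carlo simulator of the
    same chain serves as an independent validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
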
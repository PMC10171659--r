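Package: sharenet
Title: Food-Sharing Network Optimization and Starvation-Risk Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models food sharing on directed networks with a designated set of
    hunter nodes that inject food. Computes exact per-node probabilities of
    eating via first-visit random-walk probabilities and inclusion-exclusion
    over independent hunts, the exact distribution of lethal fasting runs by
    Markov chain embedding, and two starvation-risk criteria: reduction of
    variability (RV, individual risk) and welfare (WEF, egalitarian access).
    Provides (mu,lambda) evolutionary search for single-criterion local minima
    and NSGA-II multi-objective search for Pareto-optimal networks, exact
    brute-force oracles at small network sizes, a descriptive feature battery
    (degree statistics, strongly connected components, clustering, reciprocity,
    assortativity, directed modularity), Monte-Carlo protocol simulators, and
    readers/writers for edge-list and GraphML network files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
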
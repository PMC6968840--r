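Package: coalfix
Title: Coalescent Effective Size and Fixation Probability for
    Death-Birth Updating on Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constant selection on weighted, undirected graphs
    under death-Birth updating. Computes fixation probabilities exactly
    (full absorbing Markov chain), in closed form for named graph families
    (complete, star, cycle, Fan, Separated Hubs, Star of Islands), and by
    seeded Monte Carlo simulation. Solves the pairwise coalescing-random-walk
    system to obtain remeeting times and the effective population size
    N_eff = sum(pi_i * tau_i), whose first-order relationship to fixation
    probability under weak selection drives classification of graphs as
    amplifiers, suppressors, transient amplifiers, or reducers of fixation.
    Includes graph-family constructors, random-graph ensembles, a mean-field
    degree-moment approximation, and an amplifier construction that perturbs
    isothermal graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
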
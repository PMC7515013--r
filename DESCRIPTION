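Package: animats
Title: Evolvable Markov Brain Animats with Lifetime Learning and
    Integrated Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates animats controlled by Markov Brains: networks of
    genetically encoded logic gates over binary nodes. Includes
    decomposable probabilistic gates whose per-input output distributions
    factorise into independent per-bit probabilities, and decomposable
    feedback gates whose probabilities change during a lifetime in
    response to internally generated reinforcement (a model of
    neuroplasticity). Provides the indirected grid-navigation learning
    task with its 24 action-to-result mappings, a generational genetic
    algorithm with line-of-descent tracking and an elite-performer
    criterion, and integrated-information measures: atomic phi from state
    traces or transition probability matrices, and its maximum-entropy
    per-time-point variant for quantifying integration before, during and
    after learning. The episode and evolution engines are implemented in
    C++ for speed; all randomness flows through R's RNG for
    reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
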
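Package: memsearch
Title: Context-Based and Sequence-to-Sequence Models of Human Memory Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling human memory search in the free recall task.
    Implements the Context Maintenance and Retrieval (CMR) model (drifting
    context, Hebbian association matrices, context reinstatement, softmax
    retrieval) together with a gated recurrent encoder-decoder with dot-product
    attention whose retrieval rule is aligned with CMR. Provides supervised
    individual-participant fitting, proximal policy optimization of recall
    behaviour, the canonical free-recall statistics (serial position curve,
    probability of first recall, lag conditional response probability),
    Wilcoxon signed-rank and rank-biserial inference, attention heat-map
    aggregation, and fully synthetic data generators so that every analysis is
    reproducible without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
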
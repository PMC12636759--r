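Package: folde
Title: Active Learning for Low-N Protein Activity Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Model-guided directed evolution under small experimental
    budgets. Implements zero-shot mutant selection from protein language
    model naturalness (the wild-type-marginal log-likelihood ratio), a
    warm-started Bradley-Terry ranking ensemble over sequence embeddings,
    constant-liar batch acquisition with scaled observation noise, and an
    iterative simulation benchmark over deep mutational scanning
    landscapes with bootstrapped holdouts, campaign metrics (cumulative
    top-10% hits, probability of a top-1% hit) and paired Wilcoxon
    comparisons. A deterministic synthetic oracle supplies landscapes,
    per-position amino-acid log-probabilities and sequence embeddings so
    the full workflow runs without a language model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    randomForest,
    jsonlite,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'acquisition.R'
    'campaign.R'
    'fixtures.R'
    'folde-package.R'
    'landscape.R'
    'mlp.R'
    'mutations.R'
    'naturalness.R'
    'pairs.R'
    'ranker.R'
    'utils.R'
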
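Package: netbench
Title: Benchmarking Network Propagation Methods for Disease Gene Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking toolkit for network-propagation disease-gene
    prioritisation. Implements a panel of diffusion-based prioritisers on the
    regularised Laplacian kernel (raw, GeneMANIA-weighted, Monte Carlo and
    z-score normalised variants), random-walk and neighbour-voting baselines,
    positive-unlabelled kernel learners and classifiers on diffusion-state
    network embeddings; three cross-validation schemes including two
    protein-complex-aware variants that prevent label leakage through densely
    connected complexes; ranking metrics (AUROC, partial AUROC, AUPRC, top-k
    hits); quasi-likelihood explanatory models of benchmark performance with
    Tukey contrasts; rank-distance method comparison; and a synthetic-benchmark
    generator producing modular networks with planted complexes and two
    overlapping gene-disease label streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    kernlab,
    randomForest,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
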
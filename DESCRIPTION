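Package: rbmofs
Title: Binary Wrapper Feature Selection with Red-Billed Blue Magpie Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for tabular classification data driven by
    the red-billed blue magpie optimizer (RBMO) and its improved variant (IRBMO).
    Continuous swarm positions are binarized to feature masks through a fixed
    threshold or through eight S- and V-shaped transfer functions, and each mask
    is scored by a k-nearest-neighbour classifier on a stratified hold-out split,
    trading classification error against subset size. Includes confusion-matrix
    metrics, multi-run aggregation, Wilcoxon rank-sum win/tie/loss bookkeeping,
    Friedman mean-rank comparison, a synthetic data generator with planted
    informative, redundant and noise features, CSV/ARFF loaders, and a scripted
    experiment driver reproducing the 30-agent, 100-iteration, multi-run
    evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, foreign
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
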
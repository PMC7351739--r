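Package: vsvta
Title: Ventral Striatum-VTA Spike Train and Reversal-Learning Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired ventral striatum (olfactory tubercle)
    and ventral tegmental area recordings during odor-guided go/no-go reversal
    learning. Implements spike detection from multichannel voltage,
    firing-statistics cell-type classification (striatal projection neurons,
    fast-spiking and cholinergic interneurons, dopaminergic VTA units),
    sliding-window auROC response characterisation, optogenetic tagging by
    jittered cross-correlograms, across-session population-vector plasticity
    analyses (cosine/Euclidean deviation, cross-odor distances, PCA+QDA
    decoding), Q-learning models with Pearce-Hall associability and forgetting
    fitted by multistart maximum likelihood, pairwise cell-assembly detection
    with non-stationarity-robust surrogate statistics across temporal
    resolutions, and Poisson regression of assembly activity on trial-wise
    stimulus value. A synthetic-data module generates task behavior, spike
    trains, voltage and laser epochs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
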
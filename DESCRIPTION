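Package: qgnet
Title: Quantile-Graph Network Analysis of EEG Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps univariate time series (typically EEG segments) into families
    of lag-indexed weighted directed networks via the quantile-graph
    transformation, characterizes them with five topological metrics
    (weighted clustering coefficient, mean jump length, betweenness
    centrality, modularity, Laplacian Estrada index), and provides the full
    group-discrimination pipeline used for separating healthy controls from
    Alzheimer's-disease patients: median-aggregated metric-versus-lag curves,
    maximum-separation lag selection, two-level ANOVA, ROC analysis per
    channel, support-vector-machine cross-validation, and discrete-wavelet
    frequency-band decomposition. Includes a seeded synthetic EEG cohort
    generator emulating the study design (four groups, 19 channels of the
    10-20 system, 8-second segments at 128 Hz).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
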
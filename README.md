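# qgnet — quantile-graph network analysis of EEG time series

`qgnet` turns univariate time series into families of lag-indexed weighted
directed networks and uses their topology to discriminate groups of
subjects.  It was built around a concrete clinical question — separating
healthy elderly controls from Alzheimer's-disease (AD) patients using
19-channel scalp EEG — but the machinery is generic: any collection of
equal-length series with group labels can be analysed.

## The method

Given a series $X = \{x(t)\}_{t=1}^{T}$, partition its values into
$Q \approx 2T^{1/3}$ quantile intervals (nodes).  For a lag $k$, connect
node $i$ to node $j$ with weight $w^k_{ij}$ equal to the number of times
$x(t)$ lies in quantile $i$ and $x(t+k)$ in quantile $j$; the resulting
count matrix $A_k$ has total weight $T-k$.  Row-normalizing $A_k$ gives a
Markov transition matrix $W_k$.  The temporal structure of the signal —
persistence, rhythmicity, randomness — becomes network topology, which is
summarized by five metrics:

| metric | meaning |
|---|---|
| `CC`  | weighted clustering coefficient (neighbourhood closure) |
| `MJL` | mean jump length $\Delta = \frac{1}{Q}\mathrm{tr}(P W^\top)$, $p_{ij}=\lvert i-j\rvert$ |
| `BC`  | average normalized shortest-path betweenness |
| `MO`  | modularity of the best greedy partition |
| `LEE` | Laplacian Estrada index $\sum_i e^{\mu_i}$ of the symmetrized Laplacian |

Group curves metric-vs-$k$ are built on median-aggregated transition
matrices; the lag of maximum cluster separation ($k_{max}$) is selected;
per-subject metric values at $k_{max}$ feed ANOVA, Mann–Whitney ROC areas,
per-channel average AUC maps, and a cross-validated linear SVM.  A
wavelet band decomposition (delta/theta/alpha/beta) reruns the analysis
per frequency band.  A seeded synthetic cohort generator emulates the
study design (4 groups × 24 subjects × 19 channels × 1024 samples at
128 Hz) so every stage is testable without clinical data.

See `vignettes/quantile-graphs.Rmd` for the full methods account and the
reasoning behind every convention.

## Worked example

```r
library(qgnet)

# one synthetic control segment, channel F7, and its lag-1 quantile graph
seg <- generate_segment(cohort_spec(), "A", "F7", 1, seed = 1)
g   <- quantile_graph(seg, k = 1)       # Q = 20 via the cube-root rule
g
#> <qg_graph> Q=20 nodes, lag k=1, total weight 1023 (T=1024)

W <- to_markov(g)
round(sapply(qg_metrics(), function(m) qg_metric(W, m)), 4)
#>      CC     MJL      BC      MO     LEE
#>  0.7149  2.6420  0.0231  0.2769 48.2873

# full four-group cohort on one channel: curves, k_max, discrimination
coh <- generate_cohort(cohort_spec(channels = "F7"), seed = 1)
cur <- metric_curves(coh, "F7", "MJL", k_cap = 25)
km  <- select_kmax(rbind(cur$value[cur$group == "A"], cur$value[cur$group == "B"]),
                   rbind(cur$value[cur$group == "C"], cur$value[cur$group == "D"]))
km$k_max
#> [1] 4

vals <- per_segment_metrics(coh, "F7", "MJL", km$k_max)
roc_auc(vals$value[vals$group == "B"], vals$value[vals$group == "D"])
#> [1] 1
group_anova(vals$value[vals$group %in% c("A", "B")],
            vals$value[vals$group %in% c("C", "D")])
#> $F: 916.4   $p: 2.88e-50   $ci: 1.201 1.369
```

The mean jump length of the AD-like groups is larger by 1.2–1.4 units at
the selected lag (the 95% CI above), the two clusters are perfectly
separable on this channel (AUC = 1), and a 10-fold cross-validated linear
SVM on all five metrics classifies the 96 subjects with ACC 0.99 /
SEN 1.00 / SPE 0.98 / AUC 1.00:

```r
ft <- build_feature_table(coh, "F7", k_max = c(CC = 4, MJL = 4, BC = 4, MO = 4, LEE = 4))
crossval_classify(ft, folds = 10, seed = 1)[c("ACC", "SEN", "SPE", "AUC")]
```

## Command line

A thin CLI over the same functions lives at `inst/cli/qgnet.R`:

```sh
Rscript inst/cli/qgnet.R simulate --out cohort.tsv --subjects 24 --seed 1
Rscript inst/cli/qgnet.R run      --input cohort.tsv --outdir results/
Rscript inst/cli/qgnet.R bands    --input cohort.tsv --channel P3 --groups B,D
Rscript inst/cli/qgnet.R classify --features features.csv --out report.json
```

Cohorts interchange as long-format TSV (`subject`, `group`, `channel`,
`t`, `value`); graphs export as weighted edge lists or GraphML.

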
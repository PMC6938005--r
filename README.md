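# tnwclust

Clustering of temporal event sequences by temporal Needleman–Wunsch
alignment and bootstrap validation.

Many longitudinal datasets reduce each subject to a sequence of discrete
states with the time spent before each switch — a rheumatoid-arthritis
patient's biologic therapies and the months between switches, a machine's
fault codes and the hours between them. `tnwclust` stratifies such subjects:
it scores every pair of sequences with the **temporal Needleman–Wunsch
(TNW)** global alignment, clusters the resulting dissimilarities
hierarchically, selects the number of clusters by **bootstrap resampling**
with five partition-comparison indices, quantifies each cluster's stability,
and summarises clusters as transition graphs. It is written for analysts of
treatment trajectories and similar state-switch data who want a validated
stratification rather than a single dendrogram cut.

## The model

A subject is a prefix-encoded (PE) sequence `0.A,t1.B,t2.C,...`: state
symbols interleaved with inter-event durations (the reserved symbol `Z`
marks censoring). Two sequences are aligned globally under the recurrence

```
H(i,j) = max{ H(i-1,j-1) + s(x_i, y_j) - Tp * |t_x,i - t_y,j|,
              H(i-1,j) - g,
              H(i,j-1) - g }
```

with `H(i,0) = -i*g`, `H(0,j) = -j*g`: the classic Needleman–Wunsch score
(match/mismatch `s`, gap penalty `g`) minus a temporal penalty `Tp` per unit
of duration difference on every aligned pair. The N×N score matrix `S`
becomes a distance matrix `D = a - S` (with `a = max_{i<j} S_ij`),
agglomerative clustering (Ward by default) builds a dendrogram, and
bootstrap resampling decides which cut the data actually support: each
resample is re-clustered and compared with the original clustering through
the Rand, adjusted Rand, Fowlkes–Mallows, Jaccard and adjusted Wallace
indices; per-cluster stability is reported as the Jaccard index τ\*, the
recovery rate γ\* and the Dice coefficient η\* against each cluster's
best-matching bootstrap cluster.

A continuous-time Markov chain simulator (`sample_ctmc_sequence()`,
`make_two_cluster_dataset()`) generates labelled synthetic datasets for
validating the whole pipeline against known ground truth.

## Worked example

```r
library(tnwclust)

# 20 synthetic subjects: two CTMC-generated clusters of 10, known labels
ds <- make_two_cluster_dataset(n_per_cluster = 10, seed = 1)
head(ds, 3)
#> # A tibble: 3 × 5
#>   patient_id n_events pe                                  seq      label
#>   <chr>         <int> <chr>                               <list>   <int>
#> 1 S08               4 0.A,2.29427.B,0.605445.A,2.60398.B  <pe_seq>     1
#> 2 S14               6 0.C,8.57753.D,6.05014.C,2.81997.D,… <pe_seq>     2
#> 3 S09               3 0.A,2.68146.B,4.45265.A             <pe_seq>     1

# full pipeline: align (g = 0.7), cluster, validate with 100 bootstraps
sw <- run_sweep(ds, g_min = 0.7, g_max = 0.7, M = 100,
                k_min = 2, k_max = 6, seed = 1)
sw
#> <tnw_sweep> N = 20 subjects, gap grid 0.7, M = 100, linkage = ward
#>   selected k = 2 at g = 0.7
#>   cluster sizes: 10, 10

glance(sw)
#> # A tibble: 1 × 7
#>       n     k     g linkage     M  seed mean_adjusted_rand
#>   <int> <int> <dbl> <chr>   <dbl> <dbl>              <dbl>
#> 1    20     2   0.7 ward      100     1              0.944
```

Two clusters are selected; the bootstrap mean adjusted Rand of 0.944 at
k = 2 says resamples re-cluster almost identically, i.e. the 2-cluster
structure is strongly supported. `tidy(sw)` exposes the full per-(g, q,
index) table and `autoplot(sw)` plots it. The stability report confirms
both clusters are solid (γ\* is the fraction of a cluster recovered by its
best-matching bootstrap cluster):

```r
head(tibble::as_tibble(sw$stability), 3)
#> # A tibble: 3 × 6
#>   cluster  size measure median average     sd
#>     <int> <int> <chr>    <dbl>   <dbl>  <dbl>
#> 1       1    10 tau          1   0.974 0.0782
#> 2       1    10 gamma        1   0.974 0.0782
#> 3       1    10 eta          1   0.985 0.0459
```

Each final cluster summarises as a directed transition graph — edge
probability is the share of all switches in the cluster, the label the
median switch time — exportable as DOT/GraphML/CSV and plottable with
`autoplot()`:

```r
build_graph(ds$pe[sw$partition$cluster == 1])
#> # A tibble: 7 × 6
#>   from  to    count probability median_time shade
#>   <chr> <chr> <int>       <dbl>       <dbl> <dbl>
#> 1 A     B        10      0.323         2.64 0.610
#> 2 A     C         2      0.0645        2.35 0.842
#> ...
```

Real panel data enter through `panel_to_pe()` (visit-level CSV with subject
ID, state and time columns; dates or plain numbers), and `exec/tnwclust`
wraps the whole pipeline as a command-line tool
(`preprocess`, `align`, `run`, `validate`, `stability`, `visualize`).

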
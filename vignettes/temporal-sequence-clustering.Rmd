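---
title: "Clustering temporal event sequences: model, validation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering temporal event sequences: model, validation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnwclust)
```

## The problem

Longitudinal clinical records often reduce to a sequence of discrete states
per subject — which biologic drug a rheumatoid-arthritis patient is on, say —
together with the time spent before each switch. Two patients are similar
when they pass through similar states *and* on similar time scales. This
package stratifies such subjects by (1) scoring every pair of sequences with
a temporal extension of global sequence alignment, (2) clustering the
resulting dissimilarities hierarchically, and (3) deciding how many clusters
the data support — and how trustworthy each cluster is — by bootstrap
resampling.

## Prefix-encoded sequences

A subject's history is a *prefix-encoded* (PE) sequence
`0.A,t1.B,t2.C,...`: alternating inter-event durations and state symbols,
with a mandatory `0.` prefix on the first event. Time units are taken as-is
(days, months, whatever the data use) and are never rescaled; the temporal
penalty below is therefore in units of score per one time unit, and its
effective strength depends on the unit chosen. The reserved symbol `Z`
marks censoring — the final state's outcome was not observed — and is
treated as an ordinary symbol during alignment (a `Z`–`Z` pair is a match:
two subjects censored after similar histories *are* similar).

`panel_to_pe()` builds PE sequences from visit-level panel data. Consecutive
visits with the same state collapse into one event, because the model is
about state *switches*; a patient seen four times on the same drug has had
no event. Tied visit times with identical states deduplicate silently;
with conflicting states they are an error, since no ordering is defensible.

## Temporal Needleman–Wunsch alignment

For sequences $x$ and $y$ with symbols $x_i$, $y_j$ and preceding durations
$t_{x,i}$, $t_{y,j}$, the alignment score matrix is

$$
H_{i,j} = \max \begin{cases}
H_{i-1,j-1} + s(x_i, y_j) - T_p \lvert t_{x,i} - t_{y,j} \rvert \\
H_{i-1,j} - g \\
H_{i,j-1} - g
\end{cases}
$$

with $H_{0,0} = 0$, $H_{i,0} = -ig$, $H_{0,j} = -jg$. Here $s$ is the
match/mismatch score, $g \ge 0$ the gap penalty and $T_p \ge 0$ the temporal
penalty. Only substituted pairs pay the temporal term: a gap already pays
$g$, and charging gaps twice would also break the exact reduction to
classic Needleman–Wunsch at $T_p = 0$, a property the test suite pins down.
The score is the exact optimum over all global alignments — verified in the
tests against an exhaustive enumeration of alignments for short sequences —
and is symmetric in its arguments. Traceback ties prefer the diagonal move,
then the vertical, then the horizontal, making reported alignments
deterministic; tie-breaking cannot change the score.

Defaults are `match = 1`, `mismatch = -1.1`, `temporal = 0.25`, `gap = 0.7`.
The slightly super-unit mismatch makes one mismatch worse than one match is
good, so unrelated sequences drift negative; the gap default sits mid-grid
of the sweep below. All four are data-dependent knobs, which is exactly why
the pipeline sweeps `g` and validates rather than trusting any single
setting.

`similarity_matrix()` computes the $N(N-1)/2$ pairwise scores (the diagonal
is never computed and is stored as `NA`), and `to_distance()` converts
similarity to dissimilarity by $D = a - S$ with
$a = \max_{i<j} S_{ij}$, so all distances are non-negative and the most
similar pair sits at distance exactly 0.

## Clustering and bootstrap validation

`agglomerate()` delegates to `stats::hclust()` with one of five linkages
(single, complete, average, centroid, Ward). The Lance–Williams update is
applied directly to the shifted alignment distances. These are not
Euclidean, so Ward's variance interpretation (and centroid's geometric one)
is heuristic here — a caveat recorded in every JSON report the package
writes. `hclust`'s `"ward.D"` is the variant that applies the Ward
coefficients to the distances as given, which is what "directly" means
above.

Hierarchical clustering does not choose the number of clusters, so
`bootstrap_index_stats()` resamples subjects uniformly with replacement `M`
times; each resample is re-clustered from the induced sub-matrix of $D$ (no
re-alignment — scores are pairwise and fixed), both dendrograms are cut at
every $q$ in `[k_min, k_max]`, and five partition-comparison indices (Rand,
adjusted Rand, Fowlkes–Mallows, Jaccard, adjusted Wallace) are computed
between the original clustering *restricted to the resampled multiset* and
the resample's clustering. Restricting to the multiset is a deliberate
choice: the two partitions must cover the same elements, and each drawn
copy inherits the original label of the subject it copies. A `q` that the
data support yields high, low-variance indices.

Three conventions deserve note. Degenerate denominators are defined
boundedly: Jaccard and Fowlkes–Mallows are 0 when undefined, and the
chance-corrected indices are 1 for identical partitions and 0 otherwise.
The adjusted Wallace index is directional; this package fixes the direction
original → bootstrap ("of the pairs clustered together originally, how many
stay together?"), chance-corrected by the probability that a random pair is
together in the bootstrap partition; the direction is recorded in the JSON
report metadata. Third, per-cluster stability (`cluster_stability()`)
reports the Jaccard index $\tau^*$, the recovery rate $\gamma^*$ and the
Dice coefficient $\eta^*$ of each original cluster against its best-matching
bootstrap cluster (maximal overlap, multiplicities counted; ties resolved by
the larger Jaccard, then the lower cluster label). With textbook Dice and
multiset counting, $\eta^* \ge \tau^*$ always — implementations deriving
these measures differently can invert that order, so the inequality is
asserted in this package's tests to document which convention applies.

## Selecting k and g

`select_k()` implements the automatic rule: for each gap value and each
index, take the $q$ with the highest bootstrap mean; the chosen $k$ is the
modal argmax across indices (and gap values). A tie between candidates is
broken by the smaller standard deviation of the adjusted Rand at the
candidate, then by the smaller $k$ — stability and parsimony, in that
order. The chosen $g$ is the grid value with the best average index means
at that $k$. The gap grid is the plain arithmetic sequence `g_min, g_min +
g_step, ... <= g_max`. In semi-automatic mode no selection is made: the
full statistics table (`tidy()`), the per-gap dendrograms and the
`autoplot()` panels are the deliverable, and the user's `chosen_k` /
`chosen_g` feed the stability stage.

The bootstrap seed schedule derives the draws of replicate $r$ at grid
position $j$ deterministically from `(seed, j, r)`. Two consequences: runs
are bit-reproducible (the determinism tests compare written CSV files
byte-for-byte), and enlarging the grid or adding replicates never perturbs
existing draws.

## The synthetic generator

`sample_ctmc_sequence()` draws sequences from a continuous-time Markov
chain: an embedded jump chain (row-stochastic, zero diagonal), exponential
sojourns with per-state rates, an initial distribution, and an event count
drawn uniformly from a range — lengths are event counts, not elapsed time,
because PE sequences are event lists. The packaged two-cluster benchmark
(`ctmc_two_cluster_specs()`) uses alphabet {A, B, C, D}: cluster 1 starts
in {A, B} and keeps toggling A↔B with probability 0.8 per jump with mean
sojourn 2.0; cluster 2 mirrors it on {C, D} with mean sojourn 6.0; event
counts are uniform on 3..6 and there are 20 sequences per cluster. The two
groups thus differ in both symbol usage and time scale.

What this emulates — and what it does not — matters for interpreting green
tests. The generator produces exchangeable, independently sampled subjects
with stationary dynamics and exact exponential sojourns. Real treatment
histories have none of these luxuries: informative censoring, calendar
effects, never-repeat constraints on drugs, and visit-driven rather than
event-driven observation. Passing the synthetic recovery tests shows the
pipeline recovers structure *of the kind the generator produces*; it is not
evidence about any particular clinical cohort.

One property of the benchmark deserves emphasis. Because each jump leaves
the favoured pair with probability 0.2, a minority of generated sequences
genuinely wander into the other cluster's symbols; their alignment
distances place them closer to the opposite cluster, and no method scoring
symbols and durations could label them by their generator. Cluster-level
recovery (the right $k$, near-perfect adjusted Rand) is therefore robust,
while *exact* recovery of every label in a 40-subject dataset is
intrinsically limited — the recovery-rate experiment in
`scripts/acceptance.R` measures precisely this quantity, and its value
should be read with that ceiling in mind.

## Numerical choices and problem sizes

Durations are rendered with up to six significant digits in plain decimal
notation, which makes `parse_pe(format_pe(s))` the identity and keeps
written files diff-stable. Score comparisons in tests use absolute
tolerance $10^{-9}$; the dynamic program itself accumulates in double
precision with no rounding. The validation suites run at deliberately
moderate sizes — sequences of 3–6 events, 10–40 subjects, `M` of 20–200 for
unit tests and `M = 100` with 50 replicate datasets for the end-to-end
recovery experiment — sizes at which the bootstrap distributions are
already stable while the whole suite stays fast.

## Known limitations

* Ward and centroid linkage on non-Euclidean alignment distances are
  heuristics (above); single and complete linkage are always well-defined.
* There is no universal stability threshold: $\tau^*$, $\gamma^*$,
  $\eta^*$ are reported, not judged.
* The temporal penalty is linear in the time difference and unit-dependent;
  datasets with heavy-tailed durations may want rescaled time before
  encoding.
* Alignment scores are not length-normalised; very unequal sequence lengths
  are handled through the gap penalty alone, and the sweep over `g` is the
  intended control for this.
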
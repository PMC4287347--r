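---
title: "Hyperedge co-evolution analysis of dynamic functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperedge co-evolution analysis of dynamic functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercoev)
```

## The model

Functional brain networks are usually studied as static objects: one node
per brain region, one edge weight per region pair, estimated over a whole
scan. `hypercoev` implements an *edge-centric, dynamic* analysis. The scan
is cut into non-overlapping windows (60 s by default), a Pearson adjacency
matrix is computed per window, and each edge's weight is followed across
windows as a time series. Edges whose weight series rise and fall together
are *co-evolving*: the E x E matrix **X** of Pearson correlations between
edge-weight series is tested for significance, thresholded by a
Benjamini-Hochberg false-discovery-rate correction at level *q*, and
binarized. Connected components of the binarized matrix with at least two
members are **hyperedges** — sets of network edges with significantly
correlated temporal profiles. Components of size one are **singletons**
and are excluded from all further statistics. The set of hyperedges of one
subject is their hypergraph.

Downstream summaries are:

* the cumulative hyperedge **size distribution** (number of hyperedges of
  size at least *s*, pooled over subjects);
* the **hyperedge node degree** (for each region, how many hyperedges
  contain an edge touching it);
* the **co-evolution network** P, where P(i, j) is the fraction of
  hypergraphs in which edge (i, j) belongs to a hyperedge. Because
  hyperedges partition the edge set, an edge is in at most one hyperedge
  per subject, so this fraction is a probability of joint hyperedge
  membership. "Strength" of a connection always means the P entry itself.

## Task specificity

A hyperedge may co-evolve throughout a multi-task session or be driven by
one task alone. For each (hyperedge, task) pair we compute the mean
pairwise Pearson correlation between member-edge series restricted to that
task's windows, and compare it to a null distribution obtained by drawing
(without replacement) equally many windows from the *other* tasks and
recomputing the statistic. The test is one-sided — task specificity means
a *higher* within-task correlation — and the p-value uses the standard
`(1 + #{null >= obs}) / (1 + n_permutations)` correction so it is never
zero. Within one subject, all (hyperedge, task) tests form a single
Bonferroni family of size `n_hyperedges x n_tasks`. A hyperedge
significant in exactly one task joins that task's task-specific
hypergraph; significant in two or more, it is excluded from all of them;
otherwise it stays unlabeled. Null resampling happens at *window*
granularity: the member statistic is defined on the windowed edge series,
whose natural time unit is one window.

Two design points deserve emphasis. First, the null pools all non-target
windows jointly, so the p-value is invariant to how the non-target tasks
are labeled among themselves. Second, when a task has more windows than
all other tasks combined, the null cannot be formed and the test is
recorded as NA (never significant) rather than aborting the subject.

## Spatial metrics

Given node centroids (x left-right, y anterior-posterior with anterior
positive, z inferior-superior), two Pearson summaries describe where
strong co-evolution lives, both computed on the *full unthresholded* P
matrix:

* **length-strength**: R between P(i, j) and the Euclidean distance of
  centroids i and j. Negative R: strong connections are short.
* **position-strength**: R between P(i, j) and the mean y of the two
  nodes. Negative R: strong connections sit posterior.

Significance permutes strengths across connections (geometry fixed;
two-sided on |R|). Between-task comparison uses the statistic
`|R_A - R_B|` and a null that swaps the two networks' strengths
connection-wise with probability 1/2 — each connection keeps its geometry
while its task identity is exchanged. With four tasks and two metrics the
caller's Bonferroni family is 12 tests (per-test level 0.0041667 at
alpha = 0.05). Degenerate networks (fewer than three connections, or
constant strengths or covariates) yield an undefined-result marker, not a
number.

## Null models

Two surrogates separate genuine temporal structure from static statistics:

* **null overall** permutes each edge's weight series independently over
  all windows. Any hyperedge surviving it would reflect a property of the
  marginal weight distributions, not of dynamics; on planted dynamic data
  it should (and does) produce essentially no non-singleton hyperedges.
* **null within-task** permutes each edge's series independently *within*
  each task's windows. Between-task differences in weight level survive by
  construction, so edge groups with a high level in one task and a low
  level in another still form hyperedges, while purely within-task
  transient co-evolution is destroyed. The expected ordering — within-task
  null strictly between the overall null and the original counts — is what
  the test suite and the acceptance script verify.

Each row uses its own draws from one seeded stream; a common permutation
across rows would preserve all edge-edge correlations and break the null.

## The synthetic-data generator

No imaging data ships with the package; every claim is exercised on
synthetic data with *planted* co-evolution structure, generated at two
levels.

**Edge level.** A planted group is a set of node pairs, an amplitude in
[0, 1], an optional task restriction, and a baseline level. Member edge
rows are `baseline + amplitude * latent + N(0, noise_sd)`, clamped to
[-1, 1]; non-members are pure noise. The latent trajectory is the tanh of
a *standardized* Gaussian random walk: standardizing before the squash
keeps the trajectory away from saturation so it always retains usable
variance, while the walk keeps it slowly varying, which is how windowed
edge weights behave in practice. Trajectories of different groups are
decorrelated (Gram-Schmidt over shared active windows, scale preserved):
independent random walks of a few dozen steps routinely show spurious
sample correlations large enough to merge distinct planted groups, which
would make "separable groups" impossible to plant at all. A
task-restricted group's trajectory is generated directly on its own
windows, so its full variance lives inside the restricted task.

**Region level.** Each planted node *pair* receives its own carrier
signal, band-limited to 0.06-0.125 Hz so the band-pass filter passes it;
within each window both nodes mix the carrier with weight
`amplitude * (0.6 + 0.4 * latent_w)` on top of `noise_sd` of independent
band-limited activity. The windowed Pearson weight of the pair then rises
monotonically with the mixing weight, so all of a group's edge weights
co-evolve through the shared trajectory, while pairs spanning two
different planted pairs stay uncorrelated (a single group-wide carrier
would correlate *every* pair among the group's nodes, planting many more
edges than intended). With amplitude 1 and zero noise the pair's weight is
1 in every active window.

The default task ladder is four tasks (rest, attention, word, face) with
sampling periods 2, 2, 2.5, 2.5 s, so the unequal samples-per-window case
(30 vs 24 samples per 60 s window) is exercised by default. Motion traces
are nonnegative draws rescaled to an exact target mean, feeding the
0.25 mm mean-FD exclusion rule.

What the generator does *not* emulate: hemodynamic response convolution,
scanner drift and spike artifacts, spatial autocorrelation between
neighboring regions, and global signal fluctuations. Passing tests
therefore demonstrate the correctness and statistical calibration of the
pipeline on well-posed planted structure, not robustness to every
real-data pathology.

## Numerical and procedural choices

* **Butterworth order 4, zero-phase** (forward-backward via
  `signal::filtfilt`): the filter family is standard for this band; the
  order and phase handling are configuration knobs with these defaults.
  Zero-phase filtering avoids introducing inter-region lags that would
  bias windowed correlations.
* **Windows never straddle runs**; trailing samples short of a full window
  are discarded (a short window biases the Pearson estimate); filtering
  precedes windowing. Duration mode uses `floor(window_seconds / TR)`
  samples; point-count mode holds samples per window constant instead.
* **Edge indexing** is lexicographic over pairs i < j (1-based), used
  identically everywhere, so hypergraphs are comparable across subjects.
* **Edge-edge p-values** use the t transform with W - 2 degrees of
  freedom, two-sided by default so strongly anti-correlated edge series
  also link (a one-sided option exists). Constant rows get r = 0, p = 1
  with a warning rather than an error, so degenerate windows cannot abort
  a batch. BH-FDR runs once over one subject's upper-triangular p-values;
  q defaults to 0.05 and is echoed in outputs.
* **Statistical kernels** are delegated to the standard implementations —
  `stats::cor`, `stats::p.adjust(method = "BH")`, `igraph::components` —
  while the test suite checks each against an independent brute-force
  implementation (two-pass Pearson, sort-and-scan BH, boolean transitive
  closure) on ~1000 random instances.
* **Permutation tests** sample without replacement, use the +1-corrected
  p-value, and take explicit seeds; every seeded function restores the
  caller's RNG state. The pipeline derives per-stage, per-subject streams
  from one master seed via a 32-bit FNV-1a hash of a stage label, so one
  integer reproduces an entire run bit for bit.

## Hybrid-atlas refinement

Parcellations with nominally equal region sizes become unequal after
downsampling to functional resolution and signal loss. `refine_atlas()`
harmonizes a per-subject region-size table over two parcellation scales:
a region is flagged when its mean size falls below the 25th percentile of
its scale's mean sizes (threshold computed once from the input and frozen
— recomputing on the shrinking working set would flag a quarter of the
regions forever) or when its cross-subject coefficient of variation
(sample sd / mean) exceeds 30%. A flagged region is tentatively merged
with its siblings under the same coarser-scale parent; the merge is kept
iff one variability measure — the region's inter-subject CV, or the mean
within-subject size CV of the working set — strictly improves while the
other does not worsen. The canonical case this accepts is a parcel
boundary that wanders between two siblings across subjects: their sizes
are anti-correlated, so the merged region is stable on both measures.
Merges that simply create a size outlier are rejected and the offending
region is excluded (`rejected-merge`); regions with any zero-size subject
entry are excluded up front (`no-data`); CV-flagged regions with no merge
partner are excluded as `high-cv`. Reproducing any specific published
region list is out of scope — the outcome depends on the cohort's images;
the module operates purely on size tables.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at desk
scale: 8-30 nodes (28-435 edges), 32-48 windows, 50 replicate seeds for
rate estimates, and 500-1000 permutations per test. These sizes were
chosen so that every distributional claim (recovery rates, null-model
medians, permutation floors) is estimated from enough replicates to be
stable while the whole suite remains quick to run; the E x E correlation
stage itself is computed in row blocks and has been exercised up to the
E = 18721 bookkeeping implied by a 194-region parcellation (the edge-count
and window-arithmetic fixtures).

## Known limitations

* The hyperedge statistic treats all member pairs equally; very large
  hyperedges are dominated by their bulk correlation structure.
* The permutation null for task specificity mixes windows from all other
  tasks; a hyperedge strongly co-evolving in two of several tasks can
  escape significance in either (its signal contaminates the null pool),
  which makes the multi-task exclusion rule conservative.
* P is an unweighted membership fraction: one giant hyperedge and one
  tight small hyperedge contribute identically to every member edge.
* The atlas module encodes "neuroanatomically sensible groupings" purely
  as the sibling/parent forest; it cannot invent merges across parents.
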
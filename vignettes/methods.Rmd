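---
title: "Inferring directed regulatory networks from time-series expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed regulatory networks from time-series expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdminfer)
```

## The inference model

`tdminfer` reconstructs a directed gene regulatory network from
time-series expression data under a simple causal premise: if gene $x$
regulates gene $y$, then (i) $x$'s expression should change before
$y$'s, and (ii) $x$'s expression trajectory should be informative about
$y$'s trajectory a few time steps later. The pipeline operationalises
this in three steps.

**Step 1 — substantial change of expression (ScE).** For each gene $g$
with expression $g(t)$ at time points $t = 1, \dots, n$, time point
$t > 1$ is *induced* when $g(t)/g(1) > \tau$ and *repressed* when
$g(t)/g(1) < 1/\tau$, with $\tau > 1$ a ratio threshold (default 1.2).
Ratios inside the closed band $[1/\tau, \tau]$ are neutral — both
inequalities are strict, so a ratio exactly at a boundary does not
count as change. $\mathrm{ScE}(g)$ is the smallest $t$ at which $g$ is
induced or repressed. For each unordered pair $\{a, b\}$ the gene with
the smaller ScE is the candidate regulator: Case 1 keeps the ordered
pair $(a, b)$, Case 2 keeps $(b, a)$, Case 3 (equal ScE) defers both
orderings to Step 2.

**Step 2 — time-delayed mutual information.** For an ordered pair
$(x, y)$ and lag $k$,

$$I_k(x, y) = \sum_{1 \le i \le n-k} p(x_i, y_{i+k})
  \log \frac{p(x_i, y_{i+k})}{p(x_i)\, p(y_{i+k})},$$

estimated by the plug-in rule after discretizing each gene's profile
into $B$ symbols. The influence of $x$ on $y$ is
$\max_{1 \le k \le h} I_k$, with $h$ the largest lag searched (default
3). For Case 3 both orderings are evaluated and the larger influence
wins; an exact tie keeps the ordering whose source precedes the target
in identifier order (the "$\ge$" rule). The losing orientation is
discarded, so a reconstructed network can never contain reciprocal
edges.

**Step 3 — edge decision.** A directed edge $x \to y$ with weight
$\mathrm{influence}(x, y)$ is created exactly when the influence
*strictly* exceeds a threshold $\varepsilon$ (default 0.96); influence
equal to $\varepsilon$ is a predicted absent edge.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `tau` | ratio band half-width for Step 1 | 1.2 | dimensionless fold change; must exceed 1 |
| `epsilon` | influence threshold for Step 3 | 0.96 | in the units fixed by `log_base` |
| `max_lag` (h) | largest lag searched | 3 | time steps; clipped to $n - 1$ |
| `n_bins` (B) | discretization symbols | 3 | MI ceiling is $\log_2 B \approx 1.585$ bits at B = 3 |
| `binning` | `"frequency"` or `"width"` | frequency | boundary placement rule |
| `log_base` | 2 (bits) or e (nats) | 2 | recorded in every output header |

The default $\varepsilon = 0.96$ is only meaningful relative to a fixed
estimator scale. The discretization (bin count, boundary rule) and the
logarithm base jointly set that scale, and none of them is implied by
the threshold itself, so all three are explicit configuration and are
recorded in network file headers rather than silently assumed. With
the defaults ($B = 3$, bits), 0.96 sits at roughly 60% of the
theoretical MI ceiling: pairs must share well over half the resolvable
information before an edge is called.

## Numerical choices

* **Discretization.** Boundaries are computed once per gene over its
  values pooled across all series (type-7 quantiles for
  equal-frequency), not per lag window; symbols are therefore identical
  in every $I_k$, and the maximum over lags compares like with like.
  Values tied with a boundary go to the lower bin; a constant profile
  maps entirely to symbol 0 (and contributes zero MI).
* **Marginals over the overlap.** The joint and both marginals in
  $I_k$ are empirical frequencies over exactly the lag-aligned overlap
  window $i = 1 \dots n-k$ within each series. Estimating marginals on
  the full series while the joint uses the overlap can produce negative
  plug-in values; restricting all three to the same support keeps the
  estimate a true MI (non-negative up to rounding, which is clamped
  at 0).
* **Series boundaries.** Lagged pairs never span two series; with $s$
  series of $n$ points a lag-$k$ estimate uses $s(n-k)$ samples.
* **Zero and negative baselines.** The ratio rule assumes positive
  intensities. A zero baseline falls back to sign logic (positive value
  = induced, negative = repressed); if a profile contains negative
  values it is first shifted so the gene's minimum is non-negative plus
  $10^{-9}$ times the gene's range.
* **Undefined ScE.** A gene whose ratios never leave the band has no
  ScE; it is ordered as $+\infty$, since a gene that never changes
  cannot be the earlier-changing (regulating) gene of a pair. Two such
  genes fall into Case 3 and are resolved by influence like any other
  tie.
* **Tie-breaks.** `best_lag` takes the smallest lag among maxima;
  Case-3 influence ties keep the identifier-ordered pair. Both rules
  exist purely for determinism.
* **Multi-series ScE.** Each series is classified against its own first
  time point, and ScE is the minimum within-series time index across
  series. The series are independent perturbation experiments; pooling
  them against a single global baseline would compare incomparable
  starting states.
* **Identifier order.** All pair orientation and output sorting uses
  natural order (embedded integers compare numerically), so `G2 < G10
  < G100` as benchmark naming intends.

## The map/reduce engine

The three steps factor into four mapper/reducer splits — M0 (reducers
do everything), M1 (mappers run Step 1), M2 (Steps 1–2), M3 (mappers do
everything, reducers only collect). Each step is a pure function of its
key-value record, so all four algorithms produce identical networks;
the split only redistributes work between the two roles, and M2 — the
default — is the split that keeps reducers lightest. The engine runs
mappers on a local fork-based worker pool, shuffles records to
`n_reducers` partitions (default 20) by a fixed string hash so the
partitioning is reproducible across runs and machines, and executes
the remaining steps per partition. Record counts entering the
reducers are conserved — exactly $m(m-1)/2$ for M0–M2, and at most that
for M3, whose mapper-side Step 3 already drops sub-threshold pairs.
Phase timings are reported for diagnostics but are
hardware-dependent and deliberately carry no correctness weight.

## Evaluation

`score_network()` labels every ordered pair $(x, y)$, $x \ne y$, as
predicted present/absent and gold present/absent; accuracy is
$(TP + TN)/(m(m-1))$. This ordered-pair definition is the one
consistent with Step 3's explicit notion of predicted *absent* edges;
a direction error costs one FP plus one FN. Because "accuracy over
pairs" is sometimes read unordered, the scorer also reports the
unordered variant, in which either-direction presence counts as pair
presence. Gold-standard files list labelled edges; ordered pairs not
listed are absent, which turns a sparse true-edge list plus a gene
universe into a total labelling.

Two significance checks accompany the thresholds. `separation_test()`
(Student's two-sample t, equal-variance by default, Welch by flag)
checks that expression at induced time points differs in mean from
expression at repressed time points (justifying $\tau$) and that
influences of predicted-present edges differ from predicted-absent
ones (justifying $\varepsilon$). `paired_rank_test()` (Wilcoxon
signed-rank) compares accuracies of two parameter settings across the
same datasets. Degenerate inputs use fixed conventions: identical
constant groups give $p = 1$, all-zero differences give $p = 1$.

## The synthetic benchmark

The generator exists to validate the implementation end to end with a
known ground truth, and it deliberately expresses only the model class
the inference can represent: pairwise lagged dependence, one direction
per unordered pair.

`sample_network()` assigns genes a random topological order and gives
each unordered pair an edge with probability `edge_density`, oriented
along that order — acyclic by construction, never reciprocal. Each
edge carries a lag drawn from `lag_range` and an equiprobable
activation/repression sign. `simulate_timeseries()` gives every
unregulated gene a baseline (uniform in 0.8–1.2) with one randomly
timed shift per series, up or down by `effect_size` (default 3); a
regulated gene's value at $t$ is its baseline modulated by each
regulator's fold change at $t - \mathrm{lag}$ raised to the edge sign.
Multiplicative log-normal noise (`noise_sd`, default 0.1) keeps values
positive, matching the intensity semantics the ratio rule assumes.

Two generator choices deserve comment. Shift times land uniformly in
the first two-thirds of the time window: this balances the three
expression states (shifted down, baseline, shifted up) that a $B = 3$
equal-frequency discretization is meant to resolve, and leaves room for
the shift to propagate to targets within the observed window. And
shifts are per-series: with 10 independent series a pair's joint
symbol distribution is averaged over 10 shift placements, which is what
separates genuinely coupled pairs from pairs whose single-series step
patterns align by chance.

What the simulator does *not* emulate: ODE-style kinetics,
combinatorial regulation beyond independent multiplicative factors,
feedback loops, measurement-specific noise floors, or knockout designs.
Passing the recovery tests therefore shows the pipeline correctly
recovers the dependence structure it models, at realistic noise — not
that it matches any particular biological platform.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problems
chosen to exercise every code path with comfortable margins: 200
random MI instances against a brute-force oracle ($n \le 50$,
$B \le 5$); 20 seeded 15-gene datasets (5 series × 21 points) for the
M0–M3/worker/reducer equivalence checks; and ten 20-gene recovery
simulations (density 0.05, 10 series × 21 points, noise 0.1) for
accuracy and threshold-separation checks. Every random draw derives
from an explicit seed, and the whole pipeline is deterministic given
data and parameters — repeated runs write byte-identical network files
regardless of algorithm or parallelism.

The five-dataset benchmark protocol for the public DREAM4 100-gene
challenge is implemented in `run_benchmark()`; the data themselves are
third-party downloads and are not distributed with the package.

## Known limitations

* The plug-in MI estimator is biased upward at small sample counts; no
  bias correction or shuffle-null calibration is applied, so
  $\varepsilon$ implicitly absorbs the bias at the configured
  discretization. Changing $B$, the binning rule, the log base or the
  series length changes the influence scale and generally requires
  re-tuning $\varepsilon$.
* Indirect chains ($A \to B \to C$) can produce supra-threshold
  influence for $(A, C)$; no data-processing-inequality pruning is
  performed.
* Orientation rests on ScE ordering and the MI tie-break; when noise
  produces spurious early band exits in many genes, pairs collapse
  into Case 3 and orientation is decided by influence asymmetry alone.
* The engine parallelises across gene pairs on one machine; it
  preserves the partitioning algorithms' contracts but makes no claims
  about distributed storage or fault tolerance.
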
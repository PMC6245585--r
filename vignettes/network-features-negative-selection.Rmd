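---
title: "Network-derived protein features for negative example selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-derived protein features for negative example selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfeat)
```

## The problem

Gene Ontology (GO) resources record which functions a protein *has*, almost
never which functions it *lacks*. Supervised protein-function prediction
(AFP) nevertheless needs negative examples, and treating every unannotated
protein as a negative is wrong exactly for the proteins that matter: those
whose annotation simply has not been discovered yet. A temporal holdout
makes this class observable. Given an older annotation release $Y$ and a
newer one $\bar Y$ over the same proteins, the set

$$C_{np}(k) = \{ i : Y_{ik} = 0 \wedge \bar Y_{ik} = 1 \}$$

contains, for each term $k$, the proteins that looked negative in the older
release but turned out to be positive — the *unreliable* negatives. This
package asks which network-derived protein features can tell these apart
from proteins that stayed unannotated, and how well bottom-ranking
classifiers trained on such features select *reliable* negatives under a
budget.

## Network model and features

The protein network is an undirected weighted graph. STRING-style edge
lists (combined scores in 1–999) are thresholded at 700, scaled by 1/1000,
and symmetrically normalized:

$$W = D^{-1/2}\,\hat W\,D^{-1/2},\qquad d_{ii} = \sum_j \hat W_{ij},$$

which keeps $W$ symmetric with entries in $[0,1]$ and is invariant to any
global rescaling of the raw scores (so the 1/1000 convention is
inconsequential). Isolated nodes are removed before normalization.

Seventeen per-protein features are computed per GO term:

* **f1–f4** local weight statistics: neighborhood mean, sample variance
  (divisor $|N_i|-1$, 0 for a single neighbor), weighted degree, and a
  weighted clustering coefficient that averages all three edge weights of a
  closed triple; with equal weights it reduces to the classical local
  clustering coefficient (a tested invariant).
* **f5** number of annotations in the older release, excluding the current
  term (a multifunctionality proxy that must not leak the label).
* **f6–f9** geometric centralities from weighted shortest paths: closeness,
  Lin's index ($|C_i|^2$ times closeness, correcting the small-component
  bias), harmonic centrality, and betweenness (fractions of minimum-cost
  paths through the node).
* **f10–f14** term-aware counterparts: the positive-neighborhood weight
  $\sum_{j \in N_i^+} W_{ij}$ (the guilt-by-association score), its mean,
  and positive closeness / Lin / harmonic centralities over the positives
  of the node's component.
* **f15–f17** the probabilities that a random walk of length 1, 2, 3
  started at a uniformly chosen positive ends at the node, computed as
  repeated products with the row-stochastic operator
  $P = \operatorname{diag}(W\mathbf 1)^{-1} W$ (the dense cube of $P$ is
  never formed).

Each feature column is finally normalized to sum to one across proteins.
This is applied to all seventeen columns for uniformity; for f15–f17 it is
a monotone rescaling of quantities that are already probabilities.

### Numerical conventions

* **Shortest-path costs.** The feature definitions use $W$ itself as the
  cost matrix, and that literal reading (`weight_as_cost`) is the default;
  `inverse_weight`, `one_minus_weight` and `hop` are selectable for
  sensitivity analysis. Minimum-cost path counts $\sigma_{st}$ are
  accumulated in a counting Dijkstra with an absolute tie tolerance of
  1e-12 on path costs; betweenness is recovered through
  $\sigma_{st}(i) = \sigma_{si}\sigma_{it}\,[d_{si}+d_{it}=d_{st}]$.
* **Empty-set conventions.** f11 is 0 when the positive neighborhood is
  empty; f12–f14 are 0 when the node's component holds no other positive.
  When protein $i$ is itself positive, $j=i$ is excluded from the f12–f14
  distance sums (it would zero the denominators) while $|C_i^+|$ still
  counts it, matching the set definitions.
* **Duplicated columns.** In a connected network $|C_i|$ and $|C_i^+|$ are
  constant across nodes, so after sum-to-one normalization f7 duplicates f6
  and f13 duplicates f12 exactly. Deterministic tie-breaking by canonical
  feature order then channels all selections to the lower index — visible
  in relevance tables as a structural zero for f7/f13 on single-component
  networks.
* **Diameter.** Reported as the number of edges on the longest unweighted
  shortest path; the weighted diameter is the largest weighted
  shortest-path distance.

## The three experiments

**Feature relevance.** For each term with $|C_{np}| \ge 20$, the instances
are the old-release non-positives, labelled by $C_{np}$ membership. The
instances are split into three non-overlapping label-stratified subsets;
each subset runs a 3-fold outer cross-validation; on each outer-training
portion a sequential floating forward selection (SFFS) wrapped around a
CART classifier (depth-unlimited, minimum leaf size 2, no internal
pruning CV) selects a feature subset by inner 3-fold F1; F1 is used
throughout because positives are scarce. Each of the nine selection events
per term increments the selected features' counters, and features are
ranked by selection proportion. Two derived subset rules feed the negative
selection experiment: *top q* (the $q=5$ most-selected features) and
*mean* (features strictly above the mean frequency).

**Function prediction.** Per term (20–200 annotations in the newer
release), class-weighted linear SVMs (weights 1 and $(n-p)/p$) and random
forests (500 trees) are evaluated under a stratified nested 3-fold CV that
tunes $C \in \{0.01, 0.1, 1, 10, 100\}$ or $mtry$ over
$\{\lceil\sqrt d\,\rceil/2, \lceil\sqrt d\,\rceil, 2\lceil\sqrt d\,\rceil,
d/2\}$ by inner F1. A leave-one-feature-out ablation over f1–f14 measures
each feature's marginal value; the random-walk features are excluded from
the ablation. The SVM standardizes columns internally: after sum-to-one
normalization the columns have magnitude about $1/n$, on which an unscaled
linear SVM with the stated grid would collapse to the majority class.

**Negative selection.** Per term, a model trained on the older release
scores all non-positive candidates; candidates are ranked by ascending
positive-class score (SVM decision value / RF positive-class probability)
and the bottom $\lfloor x\,n/100\rfloor$, $x \in \{1,5,10,15,20,25,30\}$,
are selected as reliable negatives (budgets are floored at 1 and capped at
the pool). False negatives — selected proteins that are in $C_{np}$ — are
counted against the newer release and averaged across terms, next to the
random-selection expectation $b\,|C_{np}|/|\text{candidates}|$. Seven
feature configurations are compared: f15–f17, f1–f14, f1–f17, and the
top-q / mean reductions of the latter two.

## The synthetic benchmarks

Because the corpus experiments require dated STRING and GOA releases, the
package ships a generator whose defaults define the study conditions, and
all acceptance-grade tests run on its fixtures.

Networks are planted partitions: equally sized communities, within/between
edge probabilities, integer scores drawn as
$\mathrm{round}(701 + 298\,\mathrm{Beta}(2,2))$ so every edge survives the
standard threshold; isolated nodes are rewired into their community.
Annotations are generated per term: old-release positives are sampled in a
cyclically chosen home community, uniform noise annotations are added, and
every old-release non-positive converts to a newer-release positive with
probability $\mathrm{logit}^{-1}(\alpha + \beta z_i)$, where $z_i$ is the
standardized guilt-by-association score f10 and $\alpha$ is solved by root
finding so the expected $|C_{np}|$ hits its target (30 by default, with
bounded redraws enforcing the $\ge 20$ filter). $\beta$ is the effect
size: 0 makes conversions uniform, large values concentrate them on
high-f10 proteins.

Fixtures (all bit-reproducible from recorded seeds):

* `tiny` — 30 proteins, 2 terms; runs the whole pipeline in seconds and
  uses a `min_cnp` threshold of 5 instead of 20.
* `relevance` / `null` — 500 proteins, 60 terms, $\beta = 3$ versus
  $\beta = 0$; same seed, so the network and the older release are
  identical and only the conversion mechanism differs.
* `afp` — 450 proteins, 3 separable terms. Each term's positive class is a
  *degree-compensated bipartite planted module*: extra edges are added
  across the two halves of a randomly chosen positive set and every added
  edge deletes one outside edge per endpoint. Degrees, weight
  distributions and local clustering therefore stay flat, and the ambient
  graph is dense with lognormal hub propensities so that multi-hop routes
  through hubs dominate every direct edge — shortest-path features then
  carry almost no information about direct positive adjacency. What
  remains elevated for the positive class is precisely the
  positive-neighborhood weight f10, which is what an ablation study is
  supposed to recover. Simpler plantings fail this contract in instructive
  ways: clustered positives make f12–f14 equally informative, weight-dense
  subsets leak into f1–f3, and any design in which direct edges are
  themselves shortest paths lets a linear model reconstruct f10 from the
  contrast between harmonic and closeness scores.
* `negsel` — 300 proteins, 12 terms with $\beta$ cycling over
  $\{0.5, 1, 2, 3\}$ and annotation noise 0.05. The noise keeps the older
  release non-separable: with noise-free labels any sufficiently large SVM
  cost separates the training set exactly and the candidate tail becomes
  uncorrelated with the planted signal, which is a property of overfit
  separators rather than of the features.

What passing on these fixtures does *not* show: real STRING degree
distributions, GO term co-occurrence and ontology structure, evidence-code
biases, or the magnitude of real-data effects. The fixtures demonstrate
that every stage recovers planted structure and respects its contracts,
not that the corpus numbers would reproduce.

## Design choices on open points

* The random-walk operator is the row normalization of the *normalized*
  matrix $W$; its rows sum to one, which is what makes f15–f17
  probabilities.
* Annotation files are treated as already-propagated flat assignments; no
  ontology reasoning is performed.
* Annotations revoked between releases are kept as old-release positives
  and excluded from candidate pools — the conservative choice for a study
  of negatives.
* AFP labels come from the older release, consistent with the
  temporal-holdout training convention used by the negative-selection
  experiment.
* The relevance protocol runs SFFS once per (term, subset, outer fold),
  i.e. nine times per term, because frequencies are defined over all
  experiments on all subsets.
* For rule-based negative-selection configurations the frequency table of
  the matching pool (f1–f14 or f1–f17) must be supplied; the benchmark
  experiments use the f1–f14 pool.
* Problem sizes in the test-suite and in `scripts/acceptance.R` follow the
  fixture definitions above; the heavier corpus-scale runs are the same
  code paths on larger inputs.

## Known limitations

* Zero-cost edges (possible only under `one_minus_weight` when
  $W_{ij} = 1$) can undercount tied shortest paths.
* Dense matrices throughout: intended for networks up to a few thousand
  nodes; corpus-scale STRING networks would need sparse path machinery.
* The SFFS wrapper's inner criterion re-uses one fixed stratified fold
  assignment per selection event; criterion values across subsets of
  different sizes are therefore comparable only within an event, which is
  all the search requires.
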
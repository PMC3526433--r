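---
title: "Maximum likelihood inference of reticulate histories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum likelihood inference of reticulate histories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phynetml)
```

## The problem

When genomes exchange material horizontally — horizontal gene transfer in
prokaryotes and plants, hybridization in plants, fish and frogs — different
non-recombining genomic regions ("genes") can carry conflicting tree-like
histories, and the species history is better modeled as a *phylogenetic
network*: a rooted binary directed acyclic graph in which most nodes have a
single parent (vertical inheritance) but *reticulation nodes* have two.
Each of the two edges entering a reticulation node carries an *inheritance
probability* $\gamma$, with the pair summing to one: the probability that
any one gene was inherited through that edge.

A network $N$ *displays* a set of trees $\mathcal{T}(N)$: keep one incoming
edge per reticulation node, then suppress the degree-two nodes left behind
(this package sums the lengths of merged edges, so path lengths — and hence
likelihoods — are preserved; the displayed trees of a network with planted
transfers are exactly the SPR variants of its backbone tree). A tree $T$
may be obtainable through several induction choices, so its probability is

$$P(T \mid N, \gamma) \;=\; \sum_{\eta(T)} \prod_{e \in \eta(T)} \gamma(e),$$

summing over all induction sets yielding $T$. These probabilities always
sum to one over the displayed trees, a property the test suite asserts on
randomly generated networks.

## The likelihood

Given gene alignments $S = \{S_1, \dots, S_k\}$, the network likelihood is
the mixture, per gene, of tree likelihoods weighted by the displayed-tree
probabilities:

$$L(N, \gamma \mid S) \;=\; \prod_{S_i \in S} \; \sum_{T \in \mathcal{T}(N)}
  P(S_i \mid T)\, P(T \mid N, \gamma).$$

`network_log_likelihood()` evaluates this on the log scale with
log-sum-exp per gene. $P(S_i \mid T)$ is the Felsenstein pruning
likelihood under the Kimura (1980) two-parameter model with equal base
frequencies, uniform root distribution, and a transition/transversion
ratio of 2 by default; branch lengths are expected substitutions per site
(the rate matrix is normalized so $\alpha + 2\beta = 1$). Ambiguous bases
and gaps contribute all-ones partial likelihoods (missing data). The
pruning kernel is implemented in C++ over compressed site patterns, as the
likelihood packages in this field do.

### Branch lengths: induced, fitted, and re-optimized

Three treatments of branch lengths coexist, each with a role:

* **network-induced lengths**: each displayed tree keeps the branch
  lengths inherited from the network (subdivision halves merge back by
  summation; new transfer arcs default to length 0, modeling an
  instantaneous contemporary transfer). This makes the likelihood a pure
  function of the network and is fast enough to score the *entire*
  candidate space at every search round.
* **pooled ML fitting of the start tree** (`fit_branch_lengths()`,
  default in the search): before searching, the species tree's branch
  lengths are re-estimated by maximum likelihood on all genes pooled
  (C coordinate ascent over branches with partial-likelihood profiling).
  Without this step a candidate reticulation can gain likelihood simply
  by perturbing poorly fitting lengths instead of by explaining
  reticulate signal.
* **per-gene ML optimization** (`optimize_branches = TRUE`, and the
  search's refinement pass): every branch of a displayed tree re-fitted
  for each gene separately, the way classic ML tree programs score each
  candidate topology per locus. The optimizer is the same C routine
  (golden-section per branch on the profiled single-branch likelihood,
  preorder sweeps); it reproduces `phangorn::optim.pml` scores to better
  than 0.01 nats on test fixtures.

The per-gene mode is the statistically meaningful scale for comparing
models of different complexity — at fixed lengths, a topology-changing
candidate can still harvest residual branch-length misfit and inflate
its apparent improvement by several nats, enough to mislead BIC on
tree-like data. But it is far too slow to score hundreds of candidates
times up to 80 genes at every round. The search therefore combines the
two (next section).

## Searching network space

`forward_search()` implements forward selection over the number of
reticulations $h$. One step (`best_augmentation()`) enumerates every
ordered pair of tree edges (donor, recipient), excluding identical edges,
sibling edges (two tree edges emanating from the same node) and pairs
whose arc would close a directed cycle; each candidate subdivides both
edges at their midpoints (each half is half the original length) and adds
the arc between the midpoints. The new edge's inheritance probability is
fitted by grid search over $\{0.05, 0.10, \dots, 0.50\}$, holding the
$\gamma$ values of previously accepted edges fixed — the incremental
step of forward selection. The maximizing (edge, $\gamma$) pair is kept
and the process repeats from the augmented network.

Scoring is two-pass. Every candidate is first scored with the fast
fixed-length likelihood; the leading candidates (the top three overall
plus the three most nearly inert ones, where the fixed ranking is least
reliable) are then re-scored with per-gene branch-length-optimized tree
likelihoods, and the refined score decides the winner and enters the
trajectory. Candidates that change no displayed topology (the recipient
subtree regrafted adjacent to its own attachment) are excluded outright:
they carry no reticulate signal — under per-gene optimization their
improvement is identically zero, and under fixed lengths they act as
pure branch-length tweaks.

Implementation details that matter for cost and reproducibility:

* Candidate networks share all displayed trees that do *not* use the new
  arc with the current network, so those likelihoods are computed once per
  round; only the arc-using trees (one per induction choice of the
  existing reticulations) are scored per candidate. A per-run cache keyed
  by tree topology (and branch lengths, in fixed mode) carries scores
  across rounds.
* Node identifiers and candidate order are deterministic (internal nodes
  are ranked by their descendant-taxon sets), and ties break toward the
  earlier candidate and the smaller $\gamma$, so identical inputs always
  produce identical trajectories.

## Model selection

Augmenting a network can never decrease the optimized likelihood, so the
likelihood alone always favors more reticulations. The package scores
each level with

$$\mathrm{AIC} = 2K - 2\ln L, \qquad \mathrm{BIC} = K \ln n - 2 \ln L,$$

where $K$ is the number of branches of the network and $n$ the total
number of sites. For the *selection rule*, the criteria reduce to
thresholds on the per-step improvement when one parameter is added per
reticulation: accept the $i$-th edge iff
$\ln L(i) - \ln L(i-1) > 1$ (AIC) or $> \ln(n)/2$ (BIC).
`select_model()` applies these thresholds sequentially from $h = 0$ and
stops at the first failure (the default), matching the improvement-decay
behavior observed on the trajectories; a global-minimum mode over the
penalized scores is also available and coincides with the sequential rule
whenever the improvements decay monotonically. Note that two
conventions for $K$ coexist deliberately — the branch count for the
reported criterion values, one parameter per reticulation for the
threshold algebra: the thresholds are what define the selection
behavior.

All scores in a trajectory, including the $h = 0$ start score, are on
the refined per-gene-optimized scale, so the improvements compared with
the thresholds are mutually consistent. One subtlety of the grid: since
$\gamma \geq 0.05$, an added edge cannot be switched off entirely, so on
data without reticulate signal the best achievable improvement is about
zero and an occasional step can come out marginally negative —
"augmentation never hurts" holds exactly only when $\gamma$ may approach
0. This does not affect selection (a non-positive improvement never
passes a threshold), but trajectories should be read as approximately,
not strictly, monotone.

## The simulator and what it emulates

`simulate_hgt_dataset()` builds the study design end to end:

* **Species tree**: a 16-taxon caterpillar. The placement and
  model-selection studies use one realization, fixed once: pendant and
  internal branch lengths of 0.25, chosen so that, with the donor on taxon `t3`'s pendant edge, recipients
  `t2`, `t6` and `t8` give reticulation diameters of exactly 0.5, 1.0 and
  1.5 (measured between the attachment midpoints), with equal heights
  (0.25) across the three scenarios. The diameter-effect study uses a
  caterpillar with pendants 0.05 and internals 0.1, for which the
  fixed-donor series `t1` to `t3..t8` has diameters 0.15, 0.25, ..., 0.65.
  A seeded birth–death mode (`ape::rphylo`) is also provided.
* **Gene histories**: a planted transfer is an SPR of the species tree,
  obtained as the alternate displayed tree of the single-reticulation
  network — so the recorded truth (donor/recipient attachment, $\gamma$,
  diameter, height) is consistent with the package's own geometry by
  construction, and the test suite re-derives it independently.
* **Gene partition**: deterministic, `round(gamma * k)` genes on the
  transferred history and the rest on the species tree. For the study
  grid ($\gamma \in \{0.1, 0.3, 0.5\}$, $k \in \{10, 20, 40, 80\}$) the
  fractions are exact; rounding half-up only matters off-grid.
* **Sequences**: 100 sites per gene under K80 with ti/tv 2; the root
  sequence is drawn uniformly (the K80 stationary distribution) and
  states evolve edge by edge. All draws flow from a master seed through
  named substreams (`substream_seed()`), so every gene, replicate and
  condition is independently reproducible.

What the simulator does **not** emulate: deep coalescence (every gene
follows a displayed tree exactly), within-gene recombination, indels,
rate variation across sites, and non-uniform base composition. Passing
tests therefore demonstrate the estimator's behavior under the model's
own assumptions — reticulation as the only source of gene-tree
discordance — not robustness to the additional heterogeneity of real
data.

## Study drivers and problem sizes

The evaluation drivers run each study at 20 seeded replicates per
condition, with sample sizes chosen so the whole suite runs in tens of
minutes on one core:

* `run_placement_study()`: infer a single reticulation from the true
  species tree and score the Robinson–Foulds distance between the
  inferred alternate displayed tree and the true transferred gene tree
  (raw bipartition counts, unrooted convention). At the conditions
  (0.5, 0.3, 10), (1.0, 0.3, 40) and (1.5, 0.5, 80) the placement is
  recovered exactly (mean RF 0 over all replicates); across conditions
  the error orderings hold — non-decreasing in diameter at fixed
  (gamma, genome size), non-increasing in genome size at fixed
  (diameter, gamma).
* `run_gamma_study()`: estimate $\gamma$ with the placement fixed at the
  truth; at diameter 1.5 the modal estimate equals the true value for
  $\gamma \in \{0.1, 0.3, 0.5\}$ and the estimate variance shrinks from
  10 to 80 genes.
* `model_selection_experiment()`: forward search to $h_{\max} = 4$ on
  reticulation-free data; BIC selects 0 reticulations in every replicate
  and AIC at worst 1, with the unpenalized improvements hovering at or
  near zero (see the grid-floor note above).
* `diameter_effect_study()` / `height_effect_study()`: mean per-gene
  $\Delta \ln L$ of falsely postulated transfers; the penalty steepens
  with diameter, while height (at matched diameter) has a much smaller
  effect.

## Numerical choices and degenerate inputs

* Mixture terms are combined by log-sum-exp; pruning partials are
  rescaled per pattern when they drift below $10^{-240}$.
* Displayed trees are grouped by a canonical topology hash (children
  sorted by descendant-taxon sets); grouping for the likelihood uses
  topology *plus* branch lengths, since under fixed lengths two induction
  sets with the same topology but different lengths score differently.
* A candidate whose alternate displayed trees all repeat base topologies
  (a transfer onto an edge adjacent, in the unrooted sense, to the
  recipient's attachment) is excluded from the search as unidentifiable;
  a cheap adjacency pre-filter flags the possible cases and a topology
  hash confirms them. Should a degenerate single-reticulation network
  still reach the placement driver (e.g. from user input), it is flagged
  and scored against the base tree.
* Refined (branch-optimized) scores are deterministic but only defined
  to the optimizer's convergence tolerance (about $10^{-3}$ nats);
  candidates can tie at that resolution, in which case the deterministic
  candidate order breaks the tie.
* `gamma` exactly 0 or 1 is rejected (the grid is open on both ends);
  zero-length branches and zero-length transfer arcs are fine.
* Grid ties break toward the smaller $\gamma$ (the weaker reticulate
  signal); candidate ties break toward the deterministic enumeration
  order.

## Known limitations

* Likelihoods assume K80 with homogeneous rates; no amino-acid models,
  GTR, or site-rate heterogeneity.
* The search adds reticulations greedily and never removes or rewires
  them; it explores one trajectory, not the full network space.
* Time-consistency of transfers (donor and recipient contemporaneous) is
  not enforced — only acyclicity is.
* The gene-tree-input variant of the likelihood (scoring fixed gene trees
  against a network) is not implemented.
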
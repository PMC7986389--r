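---
title: "Weight-aware feedback vertex sets: models, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-aware feedback vertex sets: models, algorithms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmfvs)
```

## The problem

A feedback vertex set (FVS) of a directed graph is a set of vertices whose
removal leaves the graph acyclic. In directed molecular interaction networks,
FVSs are the vertex sets through which every feedback loop passes, which makes
them natural candidates for control points of the system: fixing the state of
an FVS pins down the long-term behaviour of the remaining (acyclic) network.
A minimum FVS (MFVS) is rarely unique — large interaction networks admit many
optima of identical size — so a plain MFVS solver returns an essentially
arbitrary representative, and downstream biological conclusions inherit that
arbitrariness.

This package resolves the degeneracy with vertex weights derived from data.
With genes weighted by the strength of their tumour-versus-normal
differential expression, three related problems are solved exactly:

* **MFVS** — minimise the size of the FVS (the classical problem);
* **WMFVS** — among all minimum-size FVSs, return one of maximum total
  weight;
* **WFVS** — drop the size restriction and let the weights drive the
  selection (via penalty minimisation), trading a somewhat larger set for
  heavier members.

WMFVS keeps the topological parsimony of the MFVS while using the data to
pick the most biologically plausible optimum; WFVS leans further towards the
data.

## Graph compression

Exact FVS solving is NP-hard, so the graph is first reduced by rules that
provably preserve the optima ([compress_graph()]):

* **C1.** A vertex with a self-loop is in *every* FVS. It is moved to the
  forced set ΔM and removed.
* **C2.** A vertex with no successors or no predecessors is on no cycle, so
  it is in no MFVS and can be removed.
* **C3 ("ignore").** If `v` has exactly one successor (or predecessor) `v'`,
  every cycle through `v` also passes `v'`, and breaking it at `v'` is at
  least as good. Predecessors of `v` are rewired to its successors and `v`
  is removed. A rewired arc that closes on itself becomes a self-loop and is
  harvested by C1 on the next pass.
* **SCC pruning.** Arcs joining different strongly connected components lie
  on no cycle and are deleted.

The driver applies C1, C2, C3 and SCC pruning in that priority order,
scanning vertices lexicographically, and restarts the sweep after every C3
application; the fixed point is reached when a full pass changes nothing.
The union of ΔM with any MFVS of the compressed graph is an MFVS of the
original graph.

C3 can discard *some* MFVSs — harmless when only the size matters, but not
when the maximum-weight MFVS must survive. The weighted variant
(`ignore_w`, mode `"weighted"`) therefore bypasses `v` only when all weights
are strictly positive and `v` weighs strictly less than its sole neighbour:
an exchange argument (swap `v` for `v'` in any MFVS containing `v`) shows
such a `v` is in no maximum-weight MFVS. Two deliberate choices follow the
strict form of that argument: equality of weights is **not** compressed, and
the weighted mode refuses non-positive weights outright rather than silently
skipping the rule. For WFVS, whose optima are not minimum-size sets, the C3
exchange argument does not apply at all; mode `"basic"` keeps only C1, C2
and SCC pruning, which are safe for every objective considered here.

## The integer programs and the solver

With binary membership variables `x_i` and integer ordering variables `k_i`,
an FVS is characterised by the ordering formulation: for every arc
`(v_i, v_j)`,

```
k_i - k_j + n * x_i >= 1,   0 <= k_i <= n - 1,   x_i binary.
```

Feasible `(x, k)` mark vertex sets whose removal leaves a graph that can be
ordered so that every surviving arc descends — i.e. an acyclic residual.
Three objectives over this region define the methods: minimise `sum(x_i)`
(MFVS); maximise `sum(w_i x_i)` subject to `sum(x_i) = s` with `s` the MFVS
size (WMFVS); and minimise `sum(p_i x_i)` with penalties `p` in place of
weights (WFVS).

The package ships its own exact solver for these programs: a combinatorial
branch-and-bound that branches on the vertices of a shortest cycle, applies
the always-safe reductions (forced self-loops, trimming of vertices on no
cycle) at every node, removes duplicate branches with a forbidden set, and
prunes with a vertex-disjoint-cycle lower bound (minimisation) or a top-`k`
weight relaxation (fixed-size maximisation). The ordering formulation is
used as the *certificate system*: every returned solution is converted to a
witness `(x, k)` — members at `k = 0`, the residual graph in reverse
topological order above them — and checked against every constraint, in
addition to a direct acyclicity check of the residual ([verify_fvs()]).
Solutions are never reported unverified, and a verification failure would
trigger one retry before raising an error.

Two details are worth recording. The fixed-size maximisation exploits the
fact that any superset of an FVS is an FVS: when a branch's residual graph
goes acyclic below the size budget, it is completed with the
heaviest-weight unused vertices, which is optimal for that branch; the same
top-`k` sum without the acyclicity requirement is an upper bound for
pruning. And for the minimisation problems all costs are strictly positive
(unit costs; reciprocal penalties; shifted weights), which is what makes the
trimming reduction and the early-exit bound sound.

### WFVS: penalty and shift variants

Maximising `sum(w_i x_i)` with positive weights and no size constraint is
trivial (take everything), so the weight-driven search uses one of two
reformulations:

* **Penalty (default).** Weights become penalties
  `p_i = 1 / w_i` when `w_i >= 1/l`, else `p_i = l`, with cap `l = 65536`
  standing in for the infinite penalty of a zero weight; the FVS of minimum
  total penalty is returned. Reciprocal penalties favour few, heavy
  vertices.
* **Shift.** All weights are shifted by `w_i - max(w) - eps` (default
  `eps = 1e-3`) so they are strictly negative, and the shifted total is
  maximised — equivalently, the strictly positive costs
  `max(w) + eps - w_i` are minimised.

The two objectives are genuinely different functions of the weights and can
prefer different sets; both are exposed, the penalty form as the default,
and reported objective values always state which program they optimise.
Forced self-loop vertices belong to every FVS regardless of weight, so ΔM is
united into WFVS solutions exactly as for the other methods.

## Expression-derived weights

The weight of a gene is the absolute difference in mean binary-log
expression between tumour and normal samples:
`| mean(log2 T) - mean(log2 N) |` ([fc_weight()]). Genes present in the
network but absent from the expression data keep weight 0 and are recorded
as *defaulted* rather than being removed — a topologically essential gene
with missing data can still be selected, which is one of the method's
advantages over purely expression-based ranking. Because expression counts
contain zeros and the log is otherwise undefined, [build_weight_table()]
applies the weight formula to `value + pseudocount` with a default
pseudocount of 1; set it to 0 only for strictly positive data. No
differential-expression *test* is computed here: the DEG rule
([deg_call()]) takes `|log2 FC| >= 1` together with an externally supplied
adjusted p-value `<= 0.05` (both inclusive), and works from the fold change
alone when no p-value is given.

## Evaluation statistics

Reference gene sets are compared on their **common genes** — the members
that occur in the network — which form the recall denominator;
precision divides by the prediction size.

The null model for an observed recall is an ensemble of random MFVSs
obtained by permuting the multiset of weights over the vertices (defaulted
zeros included) and re-running the WMFVS pipeline
([random_mfvs_ensemble()]). Every replicate is verified as an FVS of the
original graph with exactly the minimum size; replicates failing
verification are discarded and counted (`attempted` versus `approved`). The
empirical p-value is the plain exceedance fraction
`|{R in null : R >= R_obs}| / |null|`, so exact zeros are possible.

The enrichment score walks the weight-ranked gene list (descending weight,
lexicographic ties) adding `1/h` on the set's common genes and subtracting
`1/(N - h)` elsewhere — the canonical balanced increments that return the
running sum to 0 at the end of the list — and reports the signed
maximum-magnitude deviation. *Dark genes* are the predicted reference genes
that the DEG rule misses; their count shows what the network contributes
beyond differential expression alone.

## What the synthetic generator does and does not emulate

[random_digraph()] produces sparse Erdős–Rényi-style digraphs with planted
directed cycles (disjoint vertex runs while they last), guaranteeing a
non-trivial cyclic core whose expected MFVS size is controllable, with
positive vertex weights from uniform, log-normal or constant families.
[simulate_expression()] draws log2 expression as
`baseline + effect * [tumour] + Gaussian noise` and exponentiates, so
planted log2 shifts are recovered by the weight formula as sample counts
grow. Generation is a pure function of the spec: one seed, one graph.

These generators emulate what the algorithms care about — cycle structure,
weight heterogeneity, grouped expression with known effects — and nothing
else. They do not reproduce the degree distribution of real interactomes
(no hubs/scale-freeness), the overdispersion and library-size variation of
sequencing counts, correlated co-expression, or batch structure. Green
tests therefore certify algorithmic correctness (optimality, preservation,
calibration of the statistics), not robustness to every artefact of real
data.

## Validation design and problem sizes

Correctness is established against exhaustive oracles that share no code
path with the solver: [brute_force_all_mfvs()] enumerates subsets in
increasing size and returns *all* minimum FVSs; [brute_force_wfvs()] scans
every subset for the weighted objectives; both use an independent
Kahn-style acyclicity check, while the public [is_acyclic()] and
[scc_partition()] delegate to igraph. The test suite compares solver
answers, compression identities (`|ΔM| + MFVS(compressed) =
MFVS(original)`; preservation of the maximum MFVS weight under weighted
compression) and pipeline outputs with these oracles over a corpus of 200
seeded random digraphs of up to 10 vertices — sizes chosen so the
exhaustive enumeration itself stays exact and fast — plus hand-traced
fixtures for every reduction rule.

Weight recovery is validated on planted log2 effects of 0, 1 and 2 with 50
tumour and 50 normal samples and noise SD 0.5 over 100 seeds: the per-effect
bias of the recovered weights, averaged in absolute value across the three
effect sizes, stays below 0.05. One caveat is intrinsic to the estimator:
for a true effect of 0 the absolute value makes the recovered weight
positively biased (on the order of `sd * sqrt(2/pi) * sqrt(1/n + 1/m)`,
about 0.08 at these sizes), which is why the bias criterion averages across
effect sizes rather than demanding it per effect; at effect 1 and 2 the
estimator is unbiased.

The demonstration study in `scripts/acceptance.R` runs the whole pipeline —
network of 60 genes with five planted 3-cycles, 12 planted cancer genes with
log2 shifts between 1.5 and 3, 50 + 50 samples, a 100-replicate
shuffled-weight ensemble — and reports sizes, weights, recall/precision,
empirical p-values, the enrichment score and the dark-gene count, all
computed at run time.

## Degenerate inputs and numerical conventions

A DAG has the empty set as its (W)FVS under every method. Empty common gene
sets yield `NA` recall; empty predictions yield `NA` precision. Enrichment
is undefined (error) when a set covers none or all of the ranking. Weight
ties are broken lexicographically everywhere (rankings, top-`k` with a
warning at the boundary, solver branch order), and all "for each vertex"
loops run in lexicographic id order, so every computation in the package is
reproducible bit for bit given a seed. Optimal *objective values* are the
canonical reproducible quantity; where several optima share the objective,
the deterministic tie-breaks select one fixed representative.

## Limitations

Exact FVS optimisation is exponential in the worst case: the solver is
comfortable at the compressed-core sizes of the bundled studies (tens of
vertices, a few hundred arcs) but is not a heuristic and will not scale to
arbitrary dense graphs. The weighted compression demands strictly positive
weights, so weight tables containing exact zeros (e.g. defaulted genes)
compress under the weighted mode only after the zeros are perturbed or the
affected vertices accepted into the core — the pipelines simply refuse
rather than guess. The ensemble null is as good as its size; with 100
replicates the smallest non-zero p-value is 0.01. And the weight definition
itself is the method's main lever: weights unrelated to the biological
classification of interest yield well-optimised answers to the wrong
question.
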
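# wmfvs — weight-aware feedback vertex sets for directed biological networks

A feedback vertex set (FVS) of a directed graph is a vertex set whose removal
leaves the graph acyclic; in a directed protein interaction network it is the
set of genes through which every feedback loop passes, a natural candidate
set of control points. Minimum FVSs (MFVSs) of large networks are massively
non-unique, so a plain MFVS solver returns an arbitrary optimum and
gene-level conclusions inherit that arbitrariness. `wmfvs` removes the
degeneracy with data: genes are weighted by their tumour-versus-normal
differential expression,

```
w_v = | mean(log2 T) - mean(log2 N) |,
```

and the package computes exactly, on the ordering-formulation integer program
(`k_i - k_j + n x_i >= 1` for every arc, `x` binary),

* **MFVS** — an FVS of minimum size: minimise `sum(x_i)`;
* **WMFVS** — the maximum-weight MFVS: maximise `sum(w_i x_i)` subject to
  `sum(x_i) = s`, `s` the MFVS size;
* **WFVS** — a weight-driven FVS of unconstrained size: minimise
  `sum(p_i x_i)` with reciprocal penalties `p_i = 1/w_i` (capped at
  `l = 65536` for near-zero weights), or the negative-shift variant
  `w_i := w_i - max(w) - eps`.

Around the solvers sit the full toolchain: MFVS-preserving graph compression
with forced-vertex extraction (self-loop, periphery, single-neighbour bypass
and SCC-pruning rules, with a weight-restricted bypass that provably keeps
the maximum-weight MFVS), expression-derived weight tables with
zero-defaulting for genes missing from the data, shuffled-weight random-MFVS
null ensembles with empirical p-values, GSEA-style enrichment scores,
dark-gene analysis (reference cancer genes invisible to differential
expression), and synthetic generators plus exhaustive brute-force oracles
that validate every solver and reduction on small instances. Every returned
solution is verified — residual acyclicity plus the integer-program
certificate — before it is reported.

Audience: computational biologists prioritising candidate genes on directed
regulatory/interaction networks, and anyone needing exact weighted FVS
computation with a reproducible, verified toolchain.

## Worked example

```r
library(wmfvs)

# synthetic study: 30-gene network, 6 planted cancer genes with strong
# log2 expression shifts, 40 tumour + 40 normal samples
g0 <- random_digraph(30, p = 0.06, n_cycles = 3, seed = 11)
set.seed(12)
cancer <- sort(sample(g0$vertices, 6))
effects <- stats::setNames(numeric(30), g0$vertices)
effects[cancer] <- c(2, -1.8, 2.5, 1.6, -2.2, 1.9)
x <- simulate_expression(30, 40, 40, effect_sizes = effects, seed = 13)
w <- build_weight_table(x, g0$vertices)
g <- apply_weights(g0, w)

mfvs  <- fvs_pipeline(g, method = "MFVS")
wmfvs <- fvs_pipeline(g, method = "WMFVS")
wfvs  <- fvs_pipeline(g, method = "WFVS")
#> <fvs_solution> MFVS: 4 vertices, total weight 0.6, verified
#> <fvs_solution> WMFVS: 4 vertices, total weight 3.9, verified
#> <fvs_solution> WFVS-penalty: 4 vertices, total weight 2.6, verified

wmfvs$members
#> [1] "v02" "v05" "v07" "v24"

ens <- random_mfvs_ensemble(g, w, count = 50, seed = 14)
#> <mfvs_ensemble> 50 approved of 50 attempted (MFVS size 4)
gs <- gene_set("planted", cancer, g$vertices)
evaluate_prediction(wmfvs$members, list(gs), w, ensemble = ens)$metrics
#>       set common    recall precision p_value es
#> 1 planted      6 0.3333333       0.5    0.06  1
```

Reading the output: all three methods here need 4 genes to break every
feedback loop, but the weight-aware WMFVS picks the optimum worth 3.9 total
weight where an arbitrary MFVS is worth 0.6 — same topological cost, far
more differential-expression signal. Two of the four selected genes are
planted cancer genes (precision 0.5, recall 2/6), and only 6% of 50
random-weight MFVSs reach that recall (empirical p = 0.06). The enrichment
score 1 says the planted genes sit at the very top of the weight ranking,
i.e. the weights are highly informative for this reference set.

A command-line front end wrapping the same functions is in
`inst/cli/wmfvs` (subcommands `simulate`, `weights`, `compress`, `solve`,
`ensemble`, `evaluate`).

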
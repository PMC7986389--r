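# Small graphs used across tests, built fresh each time.

triangle <- function(w = c(a = 1, b = 2, c = 3)) {
  wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")), weights = w)
}

two_triangles <- function() {
  wdigraph(cbind(c("a", "b", "c", "d", "e", "f"),
                 c("b", "c", "a", "e", "f", "d")))
}

# Minimal instance with cycles a<->b and b<->c and weights (-2, -20, -2):
# the minimum FVS is {b} (weight -20) but the best-weight FVS is {a, c}.
seesaw_graph <- function() {
  wdigraph(cbind(c("a", "b", "b", "c"), c("b", "a", "c", "b")),
           weights = c(a = -2, b = -20, c = -2))
}

# A corpus of seeded random digraphs small enough for the exhaustive oracle.
oracle_corpus <- function(n_graphs, seed_offset = 0, n_max = 10) {
  lapply(seq_len(n_graphs), function(i) {
    n <- 4 + (i %% (n_max - 3))
    random_digraph(
      n,
      p = c(0.08, 0.15, 0.25)[1 + i %% 3],
      n_cycles = 1 + i %% 3,
      cycle_len = 2 + i %% 2,
      weight_dist = c("uniform", "lognormal", "constant")[1 + i %% 3],
      seed = seed_offset + i)
  })
}

max_mfvs_weight <- function(g, catalogue) {
  max(vapply(catalogue, function(s) sum(g$w[s]), numeric(1)))
}
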
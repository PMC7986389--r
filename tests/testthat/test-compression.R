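test_that("C1 forces self-loop vertices out of the graph", {
  g <- wdigraph(cbind(c("a", "a", "b"), c("a", "b", "a")))
  st <- rule_c1(g, "a")
  expect_identical(st$forced, "a")
  expect_identical(st$graph$vertices, "b")
  expect_equal(n_arcs(st$graph), 0L)

  # 4-arc instance a->b, b->c, c->a with a self-loop at b, traced by hand:
  # forcing b leaves only the arc c->a
  g <- wdigraph(cbind(c("a", "b", "c", "b"), c("b", "c", "a", "b")))
  st <- rule_c1(g, "b")
  expect_setequal(st$graph$vertices, c("a", "c"))
  expect_equal(st$graph$succ[["c"]], "a")
  expect_equal(n_arcs(st$graph), 1L)

  expect_error(rule_c1(triangle(), "a"), "self-loop")
})

test_that("C2 strips cycle-free periphery; a DAG compresses to nothing", {
  path <- wdigraph(cbind(c("a", "b"), c("b", "c")))
  g <- rule_c2(path, "c")
  g <- rule_c2(g, "b")
  g <- rule_c2(g, "a")
  expect_equal(n_vertices(g), 0L)
  expect_error(rule_c2(triangle(), "a"), "C2")

  star <- wdigraph(cbind(rep("hub", 3), c("l1", "l2", "l3")))
  for (leaf in c("l1", "l2", "l3")) {
    expect_s3_class(rule_c2(star, leaf), "wdigraph")
  }
  tr <- compress_graph(path, "unweighted")
  expect_equal(n_vertices(tr$compressed), 0L)
  expect_identical(tr$delta_m, character())
})

test_that("ignore rewires predecessors to successors and keeps MFVS size", {
  g <- ignore_vertex(triangle(), "a")
  expect_setequal(g$vertices, c("b", "c"))
  expect_equal(arc_matrix(g),
               cbind(from = c("b", "c"), to = c("c", "b")))
  expect_equal(brute_force_all_mfvs(g)$size, 1L)
  expect_equal(brute_force_all_mfvs(triangle())$size, 1L)

  # 2-cycle collapses to a self-loop
  g2 <- ignore_vertex(wdigraph(cbind(c("a", "b"), c("b", "a"))), "a")
  expect_identical(g2$succ[["b"]], "b")

  expect_error(ignore_vertex(wdigraph(cbind("a", "a")), "a"), "self-loop")
  dense <- wdigraph(cbind(c("a", "a", "b", "c", "b", "c"),
                          c("b", "c", "a", "a", "c", "b")))
  expect_error(ignore_vertex(dense, "a"), "single successor")
})

test_that("ignore preserves the set of cycle vertices apart from the bypassed one", {
  on_cycle <- function(g) {
    blocks <- scc_partition(g)
    big <- unlist(blocks[lengths(blocks) > 1L])
    loops <- g$vertices[vapply(g$vertices, function(v) v %in% g$succ[[v]], TRUE)]
    sort(unique(c(big, loops)))
  }
  for (seed in 1:20) {
    g <- random_digraph(8, p = 0.2, n_cycles = 2, seed = 300 + seed)
    elig <- g$vertices[vapply(g$vertices, function(v) {
      !(v %in% g$succ[[v]]) &&
        (length(g$succ[[v]]) == 1L || length(g$pred[[v]]) == 1L)
    }, TRUE)]
    if (length(elig) == 0L) next
    v <- elig[1L]
    g2 <- ignore_vertex(g, v)
    expect_lt(n_vertices(g2), n_vertices(g))
    expect_identical(setdiff(on_cycle(g), v), setdiff(on_cycle(g2), v))
  }
})

test_that("ignore_w applies only below a strictly heavier sole neighbour", {
  tri <- triangle(c(a = 1, b = 5, c = 1))
  # a: sole successor b, 1 < 5 -> applicable; optimum MFVS {b} survives
  g2 <- ignore_w(tri, "a")
  bf <- brute_force_all_mfvs(g2)
  expect_equal(max_mfvs_weight(tri, bf$catalogue), 5)
  # b is heavier than both neighbours -> not applicable
  expect_error(ignore_w(tri, "b"), "not applicable")
  # equal weights are never compressed (strict inequality)
  expect_error(ignore_w(triangle(c(a = 2, b = 2, c = 2)), "a"),
               "not applicable")
  # theorem hypothesis: positive weights only
  expect_error(ignore_w(triangle(c(a = -1, b = 5, c = 1)), "a"),
               "positive")
})

test_that("SCC pruning deletes exactly the arcs crossing components", {
  g <- wdigraph(cbind(c("a", "b", "b"), c("b", "a", "c")))
  g2 <- compress_scc(g)
  expect_equal(n_arcs(g2), 2L)
  expect_false("c" %in% g2$succ[["b"]])
  expect_setequal(g2$vertices, g$vertices)

  dag <- wdigraph(cbind(c("a", "b"), c("b", "c")))
  expect_equal(n_arcs(compress_scc(dag)), 0L)
  expect_equal(arc_matrix(compress_scc(triangle())), arc_matrix(triangle()))
})

test_that("full compression reaches a fixed point and is idempotent", {
  # self-loop plus DAG tail: everything compresses, the loop vertex is forced
  g <- wdigraph(cbind(c("a", "a", "b"), c("a", "b", "c")))
  tr <- compress_graph(g, "unweighted")
  expect_identical(tr$delta_m, "a")
  expect_equal(n_vertices(tr$compressed), 0L)

  # triangle: two ignores create a self-loop, C1 fires, |delta_m| = 1
  tr <- compress_graph(triangle(), "unweighted")
  expect_equal(length(tr$delta_m), 1L)
  expect_equal(n_vertices(tr$compressed), 0L)
  expect_equal(length(tr$delta_m) + 0L, brute_force_all_mfvs(triangle())$size)

  for (seed in 1:15) {
    g <- random_digraph(9, p = 0.2, n_cycles = 2, seed = 400 + seed)
    for (mode in c("unweighted", "weighted", "basic")) {
      tr <- compress_graph(g, mode)
      again <- compress_graph(tr$compressed, mode)
      expect_identical(again$compressed, tr$compressed)
      expect_identical(again$delta_m, character())
      expect_setequal(c(tr$compressed$vertices,
                        setdiff(tr$original_vertices, tr$compressed$vertices)),
                      g$vertices)
      expect_length(intersect(tr$delta_m, tr$compressed$vertices), 0)
    }
  }
})

test_that("weighted compression refuses non-positive weights", {
  expect_error(compress_graph(triangle(c(a = 0, b = 1, c = 1)), "weighted"),
               "offending vertex: a")
})

test_that("compression preserves MFVS size and max MFVS weight (small corpus)", {
  for (g in oracle_corpus(40, seed_offset = 500)) {
    bf <- brute_force_all_mfvs(g)
    tru <- compress_graph(g, "unweighted")
    expect_equal(length(tru$delta_m) +
                   brute_force_all_mfvs(tru$compressed)$size, bf$size)
    trw <- compress_graph(g, "weighted")
    bfc <- brute_force_all_mfvs(trw$compressed)
    expect_equal(max_mfvs_weight(g, bfc$catalogue) + sum(g$w[trw$delta_m]),
                 max_mfvs_weight(g, bf$catalogue),
                 tolerance = 1e-12)
  }
})

test_that("lifted solutions are FVSs of the original graph", {
  expect_identical(
    lift_solution(structure(list(compressed = wdigraph(), delta_m = "a"),
                            class = "compression_trace"), character()),
    "a")
  for (g in oracle_corpus(15, seed_offset = 600)) {
    tr <- compress_graph(g, "unweighted")
    sol <- if (n_vertices(tr$compressed) > 0L) {
      brute_force_all_mfvs(tr$compressed)$catalogue[[1L]]
    } else character()
    lifted <- lift_solution(tr, sol)
    expect_true(verify_fvs(g, lifted))
  }
  tr <- compress_graph(triangle(), "unweighted")
  expect_error(lift_solution(tr, "a"), "not in the compressed graph")
})
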
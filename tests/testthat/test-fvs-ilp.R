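test_that("ordering-formulation certificates accept FVSs and reject non-FVSs", {
  for (seed in 1:10) {
    g <- random_digraph(8, p = 0.2, n_cycles = 2, seed = 700 + seed)
    model <- ilp_model(g)
    bf <- brute_force_all_mfvs(g)
    for (fvs in bf$catalogue[seq_len(min(3, length(bf$catalogue)))]) {
      cert <- ilp_certificate(g, fvs)
      expect_false(is.null(cert))
      expect_true(ilp_feasible(model, cert$x, cert$k))
      # padding an FVS keeps feasibility
      sup <- union(fvs, setdiff(g$vertices, fvs)[1])
      cert2 <- ilp_certificate(g, sup)
      expect_true(ilp_feasible(model, cert2$x, cert2$k))
    }
    if (bf$size > 0L) {
      expect_null(ilp_certificate(g, character()))
    }
  }
  expect_error(ilp_model(wdigraph(cbind("a", "a"))), "self-loop")
})

test_that("minimum FVS size matches the exhaustive oracle", {
  expect_equal(solve_mfvs_size(triangle())$size, 1L)
  expect_equal(solve_mfvs_size(two_triangles())$size, 2L)
  for (g in oracle_corpus(30, seed_offset = 800)) {
    sol <- solve_mfvs_size(g)
    expect_equal(sol$size, brute_force_all_mfvs(g)$size)
    expect_true(sol$verified)
    expect_true(verify_fvs(g, sol$members))
  }
})

test_that("fixed-size maximum-weight solve matches the oracle and flags infeasibility", {
  sol <- solve_wmfvs(triangle(), 1)
  expect_identical(sol$members, "c")
  expect_equal(sol$total_weight, 3)

  const <- triangle(c(a = 2, b = 2, c = 2))
  expect_equal(solve_wmfvs(const, 1)$total_weight, 2)

  expect_error(solve_wmfvs(two_triangles(), 1), "infeasible")

  for (g in oracle_corpus(25, seed_offset = 900)) {
    bf <- brute_force_all_mfvs(g)
    sol <- solve_wmfvs(g, bf$size)
    expect_equal(sol$size, bf$size)
    expect_equal(sol$total_weight, max_mfvs_weight(g, bf$catalogue),
                 tolerance = 1e-9)
    expect_true(verify_fvs(g, sol$members))
  }
})

test_that("raising a chosen vertex's weight never lowers the fixed-size optimum", {
  for (seed in 1:8) {
    g <- random_digraph(8, p = 0.2, n_cycles = 2, seed = 1000 + seed)
    s <- solve_mfvs_size(g)$size
    if (s == 0L) next
    base <- solve_wmfvs(g, s)
    w2 <- g$w
    w2[base$members[1L]] <- w2[base$members[1L]] + 1
    bumped <- solve_wmfvs(apply_weights(g, w2), s)
    expect_gte(bumped$total_weight + 1e-9, base$total_weight)
  }
})

test_that("penalty transform inverts weights with the documented cap", {
  p <- penalty_transform(c(a = 2, b = 0, c = 1e-5))
  expect_equal(unname(p$entries), c(0.5, 65536, 65536))
  expect_equal(p$cap, 65536)
  expect_warning(penalty_transform(c(a = -1)), "negative")
  expect_equal(unname(penalty_transform(c(a = 4), l = 10)$entries), 0.25)
})

test_that("penalty-minimising FVS matches the oracle", {
  sol <- solve_wfvs_penalty(triangle(), penalty_transform(triangle()$w))
  expect_identical(sol$members, "c")
  expect_equal(sol$objective_value, 1 / 3, tolerance = 1e-12)

  dag <- wdigraph(cbind(c("a", "b"), c("b", "c")), weights = c(a = 1, b = 1, c = 1))
  sol <- solve_wfvs_penalty(dag, penalty_transform(dag$w))
  expect_identical(sol$members, character())
  expect_equal(sol$objective_value, 0)

  for (g in oracle_corpus(25, seed_offset = 1100)) {
    pen <- penalty_transform(g$w)
    sol <- solve_wfvs_penalty(g, pen)
    bf <- brute_force_wfvs(g, pen$entries, "min_penalty")
    expect_equal(sol$objective_value, bf$value, tolerance = 1e-9)
    expect_true(verify_fvs(g, sol$members))
  }
})

test_that("negative-shift FVS maximises original weight over all FVSs", {
  # weights (-2, -20, -2) on cycles a<->b, b<->c: {a, c} at -4 beats {b} at -20
  sol <- solve_wfvs_shift(seesaw_graph())
  expect_identical(sol$members, c("a", "c"))
  expect_equal(sol$total_weight, -4)

  sol <- solve_wfvs_shift(triangle(), epsilon = 0.001)
  expect_identical(sol$members, "c")

  expect_identical(
    solve_wfvs_shift(wdigraph(cbind(c("a", "b"), c("b", "c"))))$members,
    character())

  for (g in oracle_corpus(20, seed_offset = 1200)) {
    sol <- solve_wfvs_shift(g, epsilon = 1e-3)
    # the shift optimum is a max-weight FVS among minimal-blame sets; compare
    # through the equivalent positive-cost objective
    cost <- max(g$w) + 1e-3 - g$w
    bf <- brute_force_wfvs(g, cost, "min_penalty")
    expect_equal(sum(cost[sol$members]), bf$value, tolerance = 1e-9)
  }
})

test_that("verify_fvs is removal-then-acyclicity", {
  expect_true(verify_fvs(triangle(), "a"))
  expect_false(verify_fvs(triangle(), character()))
  expect_true(verify_fvs(two_triangles(), c("a", "d")))
  expect_error(verify_fvs(triangle(), "zz"), "graph vertices")
})

test_that("the full pipeline compresses, solves, lifts and verifies", {
  dag <- wdigraph(cbind(c("a", "b"), c("b", "c")), weights = c(a = 1, b = 1, c = 1))
  for (m in c("MFVS", "WMFVS", "WFVS")) {
    expect_identical(fvs_pipeline(dag, method = m)$members, character())
  }

  for (g in oracle_corpus(20, seed_offset = 1300)) {
    bf <- brute_force_all_mfvs(g)
    mf <- fvs_pipeline(g, method = "MFVS")
    expect_equal(mf$size, bf$size)
    expect_true(verify_fvs(g, mf$members))

    wm <- fvs_pipeline(g, method = "WMFVS")
    expect_equal(wm$size, bf$size)
    expect_equal(wm$total_weight, max_mfvs_weight(g, bf$catalogue),
                 tolerance = 1e-9)

    wf <- fvs_pipeline(g, method = "WFVS")
    expect_true(verify_fvs(g, wf$members))
    expect_gte(wf$size, mf$size)
    expect_gte(wf$total_weight, 0)
    bfp <- brute_force_wfvs(g, penalty_transform(g$w)$entries, "min_penalty")
    expect_equal(wf$objective_value, bfp$value, tolerance = 1e-9)
  }
})

test_that("pipeline handles graphs with self-loops via forced vertices", {
  g <- wdigraph(cbind(c("a", "a", "b", "c"), c("a", "b", "c", "b")),
                weights = c(a = 1, b = 2, c = 3))
  sol <- fvs_pipeline(g, method = "WMFVS")
  expect_true("a" %in% sol$members)
  expect_true(verify_fvs(g, sol$members))
  tr <- attr(sol, "trace")
  expect_true("a" %in% tr$delta_m)
})
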
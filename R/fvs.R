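#' Ordering-formulation integer program for feedback vertex sets
#'
#' The feedback vertex set problem on a digraph with `n` vertices is encoded
#' with a binary membership variable `x_i` and an integer ordering variable
#' `k_i` per vertex: for every arc `(v_i, v_j)`,
#' `k_i - k_j + n * x_i >= 1`, with `0 <= k_i <= n - 1`. If `x` marks an FVS,
#' the residual graph is acyclic and a topological order supplies feasible
#' `k`; conversely any feasible `(x, k)` forces every cycle to contain a
#' marked vertex. Objectives over this feasible region give the three
#' problems solved here: minimise `sum(x)` (MFVS size), maximise
#' `sum(w * x)` at fixed size `s` (maximum-weight MFVS), and minimise
#' `sum(p * x)` for penalties `p` (weight-driven FVS of free size).
#'
#' `ilp_model()` materialises the constraint system; `ilp_certificate()`
#' constructs the witness `(x, k)` for a vertex set (topological order of the
#' residual graph) and `ilp_feasible()` checks a `(x, k)` pair against every
#' constraint. The package's exact branch-and-bound solver returns solutions
#' whose certificates are checked this way.
#'
#' @param g a [wdigraph()] without self-loops (compression extracts
#'   self-loops into delta-M first).
#' @return `ilp_model()`: list with `vertices`, `arcs` (two-column matrix of
#'   vertex indices), and `n`. `ilp_certificate()`: list with named binary
#'   `x` and integer `k`, or `NULL` when `members` is not an FVS.
#'   `ilp_feasible()`: logical.
#' @name fvs_ilp
#' @export
ilp_model <- function(g) {
  if (any(vapply(g$vertices, has_self_loop, TRUE, g = g))) {
    stop("ILP formulation requires a self-loop-free graph; compress first")
  }
  am <- arc_matrix(g)
  idx <- stats::setNames(seq_along(g$vertices), g$vertices)
  list(vertices = g$vertices,
       arcs = cbind(from = unname(idx[am[, 1L]]), to = unname(idx[am[, 2L]])),
       n = length(g$vertices))
}

#' @rdname fvs_ilp
#' @param members character vector of vertex ids (candidate FVS).
#' @export
ilp_certificate <- function(g, members) {
  model <- ilp_model(g)
  members <- as.character(members)
  if (!all(members %in% g$vertices)) stop("members must be graph vertices")
  residual <- if (length(members) > 0L) remove_vertex(g, members) else g
  if (!is_acyclic(residual)) return(NULL)
  # Constraints read k_i >= k_j + 1 along unmarked arcs, so k must DECREASE
  # along a topological order of the residual graph; members sit at k = 0,
  # strictly below every residual vertex, covering arcs into the FVS.
  k <- stats::setNames(integer(model$n), g$vertices)
  if (n_vertices(residual) > 0L) {
    topo <- names(igraph::topo_sort(as_igraph(residual), mode = "out"))
    offset <- if (length(members) > 0L) 1L else 0L
    k[topo] <- length(topo) - seq_along(topo) + offset
  }
  x <- stats::setNames(as.integer(g$vertices %in% members), g$vertices)
  list(x = x, k = k)
}

#' @rdname fvs_ilp
#' @param model an `ilp_model()`.
#' @param x named binary vector (FVS membership indicators).
#' @param k named integer vector (ordering variables).
#' @export
ilp_feasible <- function(model, x, k) {
  x <- x[model$vertices]; k <- k[model$vertices]
  if (anyNA(x) || anyNA(k)) return(FALSE)
  if (!all(x %in% c(0L, 1L))) return(FALSE)
  if (any(k < 0L) || any(k > model$n - 1L)) return(FALSE)
  if (nrow(model$arcs) == 0L) return(TRUE)
  all(k[model$arcs[, 1L]] - k[model$arcs[, 2L]] +
        model$n * x[model$arcs[, 1L]] >= 1)
}

new_fvs_solution <- function(g, members, method, objective_value) {
  members <- sort(as.character(members))
  structure(list(members = members,
                 method = method,
                 size = length(members),
                 total_weight = sum(g$w[members]),
                 objective_value = objective_value,
                 verified = verify_fvs(g, members)),
            class = "fvs_solution")
}

#' @export
print.fvs_solution <- function(x, ...) {
  cat(sprintf("<fvs_solution> %s: %d vertices, total weight %.1f%s\n",
              x$method, x$size, x$total_weight,
              if (isTRUE(x$verified)) ", verified" else ", NOT VERIFIED"))
  invisible(x)
}

#' Verify a feedback vertex set
#'
#' @param g a [wdigraph()].
#' @param members character vector of vertex ids, subset of `g`'s vertices.
#' @return `TRUE` iff removing `members` leaves `g` acyclic. All solver
#'   outputs in this package are re-checked with this predicate (solutions
#'   are never trusted unverified).
#' @export
verify_fvs <- function(g, members) {
  members <- as.character(members)
  if (!all(members %in% g$vertices)) stop("members must be graph vertices")
  residual <- if (length(members) > 0L) remove_vertex(g, members) else g
  is_acyclic(residual)
}

solve_with_verification <- function(g, solve_fun, method, retries = 1L) {
  for (attempt in seq_len(retries + 1L)) {
    res <- solve_fun()
    sol <- new_fvs_solution(g, res$members, method, res$value)
    cert <- ilp_certificate(g, sol$members)
    if (isTRUE(sol$verified) && !is.null(cert) &&
        ilp_feasible(ilp_model(g), cert$x, cert$k)) {
      return(sol)
    }
  }
  stop("solver returned a set that failed FVS verification after retry")
}

#' Solve the minimum feedback vertex set size (ILP1 objective)
#'
#' @param g a [wdigraph()] without self-loops.
#' @return An `fvs_solution` (method `"MFVS"`): `$size` is the minimum FVS
#'   cardinality, `$members` one optimal set, `$verified` always `TRUE`.
#' @examples
#' g <- wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' solve_mfvs_size(g)$size
#' @export
solve_mfvs_size <- function(g) {
  ilp_model(g) # validates no self-loops
  ig <- int_graph(g)
  solve_with_verification(g, function() {
    res <- bb_min_cost_fvs(ig, rep(1, ig$n))
    list(members = ig$ids[res$members], value = res$value)
  }, "MFVS")
}

#' Solve the maximum-weight MFVS at fixed size (ILP2 objective)
#'
#' Maximises total vertex weight over all FVSs of size exactly `s`. With
#' `s` equal to the minimum FVS size this selects the maximum-weight MFVS.
#'
#' @param g a [wdigraph()] without self-loops, with weights attached.
#' @param s target FVS size, normally `solve_mfvs_size(g)$size`.
#' @return An `fvs_solution` (method `"WMFVS"`); `$objective_value` equals
#'   `$total_weight`. Errors with "infeasible" when `s` is below the true
#'   minimum FVS size.
#' @export
solve_wmfvs <- function(g, s) {
  ilp_model(g)
  stopifnot(length(s) == 1L, s >= 0, s == round(s))
  ig <- int_graph(g)
  w <- unname(g$w[ig$ids])
  solve_with_verification(g, function() {
    res <- bb_max_weight_fixed_size(ig, w, as.integer(s))
    if (is.null(res)) {
      stop("infeasible: no FVS of size ", s,
           " exists (below the minimum FVS size)")
    }
    list(members = ig$ids[res$members], value = res$value)
  }, "WMFVS")
}

#' Penalty transform for weight-driven FVS search (ILP3')
#'
#' Maximising total weight over FVSs of unconstrained size is trivial for
#' positive weights (take every vertex), so weights are inverted into
#' penalties that are then minimised: `p_i = 1 / w_i` when `w_i >= 1/l`,
#' else `p_i = l`, with the cap `l` replacing the infinite penalty of a
#' zero weight.
#'
#' @param w a [weight_table()] or named numeric vector.
#' @param l penalty cap, a large positive number (default 65536).
#' @return A `penalty_table`: list with `entries` (named positive penalties)
#'   and `cap`.
#' @examples
#' penalty_transform(c(a = 2, b = 0))$entries
#' @export
penalty_transform <- function(w, l = 65536) {
  stopifnot(l > 0)
  entries <- if (inherits(w, "weight_table")) w$entries else w
  if (any(entries < 0)) {
    warning(sum(entries < 0), " negative weight(s) mapped to the penalty cap")
  }
  p <- ifelse(entries >= 1 / l, 1 / entries, l)
  structure(list(entries = stats::setNames(as.numeric(p), names(entries)),
                 cap = l),
            class = "penalty_table")
}

#' @export
print.penalty_table <- function(x, ...) {
  cat(sprintf("<penalty_table> %d entries, cap l = %g\n",
              length(x$entries), x$cap))
  invisible(x)
}

#' Weight-driven FVS via penalty minimisation (ILP3')
#'
#' Finds the FVS (any size) minimising the total penalty
#' `sum(p_i * x_i)` under the ordering constraints; with reciprocal
#' penalties this favours few, heavy vertices. This is the default
#' weight-driven FVS method.
#'
#' @param g a [wdigraph()] without self-loops.
#' @param p a `penalty_table` from [penalty_transform()] covering all
#'   vertices of `g` (missing vertices get the cap).
#' @return An `fvs_solution` (method `"WFVS-penalty"`); `$objective_value`
#'   is the minimised penalty sum, `$total_weight` uses the graph's original
#'   weights.
#' @export
solve_wfvs_penalty <- function(g, p) {
  ilp_model(g)
  stopifnot(inherits(p, "penalty_table"))
  pen <- stats::setNames(rep(p$cap, n_vertices(g)), g$vertices)
  hit <- intersect(g$vertices, names(p$entries))
  pen[hit] <- p$entries[hit]
  if (any(pen <= 0)) stop("penalties must be strictly positive")
  ig <- int_graph(g)
  solve_with_verification(g, function() {
    res <- bb_min_cost_fvs(ig, unname(pen[ig$ids]))
    list(members = ig$ids[res$members], value = res$value)
  }, "WFVS-penalty")
}

#' Weight-driven FVS via the negative shift (ILP3)
#'
#' Shifts every weight by `w_i - max(w) - epsilon` so all weights become
#' negative, then maximises the shifted total over FVSs of unconstrained
#' size; equivalently, minimises the positive costs
#' `max(w) + epsilon - w_i`. The alternative to the (default) penalty
#' method.
#'
#' @param g a [wdigraph()] without self-loops.
#' @param w a [weight_table()] or named numeric vector; vertices without an
#'   entry use the graph's stored weight.
#' @param epsilon small positive shift margin (default `1e-3`).
#' @return An `fvs_solution` (method `"WFVS-shift"`); `$objective_value` is
#'   the maximised shifted objective (non-positive), `$total_weight` uses
#'   the original weights.
#' @export
solve_wfvs_shift <- function(g, w = NULL, epsilon = 1e-3) {
  ilp_model(g)
  stopifnot(epsilon > 0)
  if (!is.null(w)) g <- apply_weights(g, w)
  if (n_vertices(g) == 0L) {
    return(new_fvs_solution(g, character(), "WFVS-shift", 0))
  }
  wm <- max(g$w)
  cost <- wm + epsilon - g$w # strictly positive
  ig <- int_graph(g)
  solve_with_verification(g, function() {
    res <- bb_min_cost_fvs(ig, unname(cost[ig$ids]))
    list(members = ig$ids[res$members], value = -res$value)
  }, "WFVS-shift")
}

#' Full compress-solve-lift-verify pipeline
#'
#' Runs one of the three methods end to end on an arbitrary weighted digraph
#' (self-loops allowed: compression extracts them into the forced set
#' delta-M, which is united back into the solution):
#'
#' * `"MFVS"` — unweighted compression (`ignore` bypass), minimise size.
#' * `"WMFVS"` — weighted compression (`ignore_w` bypass; strictly positive
#'   weights required), minimise size, then maximise weight at that size.
#' * `"WFVS"` — basic compression (C1/C2/SCC pruning only), penalty
#'   minimisation (or the negative-shift variant).
#'
#' The lifted solution is verified against the *original* graph; the
#' returned object's weights and sizes refer to the original graph.
#'
#' @param g a [wdigraph()].
#' @param w optional [weight_table()] applied to `g` first (required weights
#'   may also already live on `g`).
#' @param method `"MFVS"`, `"WMFVS"` or `"WFVS"`.
#' @param l penalty cap for the WFVS penalty transform.
#' @param epsilon shift margin for `wfvs_variant = "shift"`.
#' @param wfvs_variant `"penalty"` (default) or `"shift"`.
#' @return An `fvs_solution` on the original graph. The attribute
#'   `"trace"` carries the [compress_graph()] trace (including delta-M).
#' @examples
#' g <- wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")),
#'               weights = c(a = 1, b = 2, c = 3))
#' fvs_pipeline(g, method = "WMFVS")$members
#' @export
fvs_pipeline <- function(g, w = NULL, method = c("MFVS", "WMFVS", "WFVS"),
                         l = 65536, epsilon = 1e-3,
                         wfvs_variant = c("penalty", "shift")) {
  method <- match.arg(method)
  wfvs_variant <- match.arg(wfvs_variant)
  if (!is.null(w)) g <- apply_weights(g, w)
  mode <- switch(method, MFVS = "unweighted", WMFVS = "weighted",
                 WFVS = "basic")
  trace <- compress_graph(g, mode)
  core <- trace$compressed
  members <- if (n_vertices(core) == 0L || is_acyclic(core)) {
    character()
  } else if (method == "MFVS") {
    solve_mfvs_size(core)$members
  } else if (method == "WMFVS") {
    s <- solve_mfvs_size(core)$size
    solve_wmfvs(core, s)$members
  } else if (wfvs_variant == "penalty") {
    solve_wfvs_penalty(core, penalty_transform(core$w, l))$members
  } else {
    solve_wfvs_shift(core, epsilon = epsilon)$members
  }
  lifted <- lift_solution(trace, members)
  objective <- switch(
    method,
    MFVS = length(lifted),
    WMFVS = sum(g$w[lifted]),
    WFVS = if (wfvs_variant == "penalty") {
      sum(penalty_transform(g$w, l)$entries[lifted])
    } else {
      if (n_vertices(g) == 0L) 0 else
        sum(g$w[lifted] - max(g$w) - epsilon)
    })
  method_tag <- switch(method, MFVS = "MFVS", WMFVS = "WMFVS",
                       WFVS = paste0("WFVS-", wfvs_variant))
  sol <- new_fvs_solution(g, lifted, method_tag, objective)
  if (!isTRUE(sol$verified)) {
    stop("pipeline produced a set that is not an FVS of the original graph")
  }
  attr(sol, "trace") <- trace
  sol
}
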
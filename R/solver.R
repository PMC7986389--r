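# Internal exact solver machinery for feedback vertex set optimisation.
#
# The three integer programs (minimise |S|; maximise weight at fixed size;
# minimise penalty) are solved exactly by combinatorial branch-and-bound:
# branch on the vertices of a shortest cycle, with the always-safe reductions
# (forced self-loops, trimming of acyclic periphery) applied at every node,
# duplicate branches cut by a forbidden set, and bounds from vertex-disjoint
# cycles (minimisation) or a top-k weight relaxation (fixed-size
# maximisation). All tie-breaks are deterministic (lexicographic vertex
# order), so solver output is reproducible.

int_graph <- function(g) {
  ids <- g$vertices
  idx <- stats::setNames(seq_along(ids), ids)
  list(n = length(ids),
       ids = ids,
       succ = lapply(g$succ, function(s) unname(idx[s])),
       pred = lapply(g$pred, function(p) unname(idx[p])))
}

# Kahn-style acyclicity check on the alive-induced subgraph. Independent of
# igraph so oracle and implementation cross-check through different routes.
ig_acyclic <- function(ig, alive) {
  indeg <- integer(ig$n)
  for (i in which(alive)) {
    s <- ig$succ[[i]]
    s <- s[alive[s]]
    indeg[s] <- indeg[s] + 1L
    if (i %in% s) return(FALSE) # self-loop
  }
  queue <- which(alive & indeg == 0L)
  seen <- 0L
  total <- sum(alive)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (s in ig$succ[[v]]) {
      if (alive[s]) {
        indeg[s] <- indeg[s] - 1L
        if (indeg[s] == 0L) queue <- c(queue, s)
      }
    }
  }
  seen == total
}

# Shortest directed cycle in the alive-induced subgraph, as an integer vertex
# sequence (no self-loops expected: callers force those first). NULL if
# acyclic. BFS from every alive vertex; early exit on a 2-cycle.
ig_shortest_cycle <- function(ig, alive) {
  best <- NULL
  for (root in which(alive)) {
    dist <- rep(NA_integer_, ig$n)
    par <- integer(ig$n)
    queue <- c(ig$succ[[root]][alive[ig$succ[[root]]]])
    for (q in queue) if (is.na(dist[q])) { dist[q] <- 1L; par[q] <- root }
    queue <- unique(queue)
    found <- FALSE
    while (length(queue) > 0L && !found) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.null(best) && dist[v] + 1L >= length(best)) next
      for (s in ig$succ[[v]]) {
        if (!alive[s]) next
        if (s == root) {
          cyc <- v
          while (cyc[1L] != root) cyc <- c(par[cyc[1L]], cyc)
          best <- cyc
          found <- TRUE
          break
        }
        if (is.na(dist[s])) {
          dist[s] <- dist[v] + 1L
          par[s] <- v
          queue <- c(queue, s)
        }
      }
    }
    if (!is.null(best) && length(best) == 2L) break
  }
  best
}

# Any directed cycle (iterative DFS); cheaper than shortest, used for bounds.
ig_any_cycle <- function(ig, alive) {
  color <- integer(ig$n) # 0 white, 1 on stack, 2 done
  for (root in which(alive)) {
    if (color[root] != 0L) next
    stack <- list(list(v = root, i = 0L))
    path <- integer()
    color[root] <- 1L
    path <- root
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      s <- top$v
      nxt <- ig$succ[[s]]
      nxt <- nxt[alive[nxt]]
      if (top$i < length(nxt)) {
        stack[[length(stack)]]$i <- top$i + 1L
        u <- nxt[top$i + 1L]
        if (color[u] == 1L) {
          k <- match(u, path)
          return(path[k:length(path)])
        }
        if (color[u] == 0L) {
          color[u] <- 1L
          path <- c(path, u)
          stack[[length(stack) + 1L]] <- list(v = u, i = 0L)
        }
      } else {
        color[s] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# Lower bound for min-cost FVS: greedy vertex-disjoint cycles, each charged
# its cheapest non-forbidden vertex. Inf when some cycle is all-forbidden.
ig_lower_bound <- function(ig, alive, forb, cost) {
  lb <- 0
  avail <- alive
  repeat {
    cyc <- ig_any_cycle(ig, avail)
    if (is.null(cyc)) return(lb)
    open <- cyc[!forb[cyc]]
    if (length(open) == 0L) return(Inf)
    lb <- lb + min(cost[open])
    avail[cyc] <- FALSE
  }
}

# Reductions at a branch-and-bound node: force self-loops into the solution
# (infeasible if forbidden), trim vertices with no alive successor or
# predecessor. Returns updated state or NULL when the branch is infeasible.
ig_reduce <- function(ig, alive, forb, chosen) {
  repeat {
    changed <- FALSE
    for (i in which(alive)) {
      s <- ig$succ[[i]]
      if (i %in% s[alive[s]]) {
        if (forb[i]) return(NULL)
        alive[i] <- FALSE
        chosen <- c(chosen, i)
        changed <- TRUE
      }
    }
    for (i in which(alive)) {
      s <- ig$succ[[i]]; p <- ig$pred[[i]]
      if (sum(alive[s]) == 0L || sum(alive[p]) == 0L) {
        alive[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(alive = alive, chosen = chosen)
}

# Exact minimum-cost FVS, costs strictly positive. Returns integer indices.
bb_min_cost_fvs <- function(ig, cost) {
  stopifnot(all(cost > 0))
  best <- new.env(parent = emptyenv())
  best$value <- Inf
  best$members <- integer()

  recurse <- function(alive, forb, chosen, acc) {
    red <- ig_reduce(ig, alive, forb, chosen)
    if (is.null(red)) return(invisible())
    alive <- red$alive
    newly <- setdiff(red$chosen, chosen)
    acc <- acc + sum(cost[newly])
    chosen <- red$chosen
    if (acc >= best$value) return(invisible())
    cyc <- ig_shortest_cycle(ig, alive)
    if (is.null(cyc)) {
      if (acc < best$value) {
        best$value <- acc
        best$members <- sort(chosen)
      }
      return(invisible())
    }
    lb <- ig_lower_bound(ig, alive, forb, cost)
    if (acc + lb >= best$value) return(invisible())
    cand <- cyc[!forb[cyc]]
    if (length(cand) == 0L) return(invisible())
    cand <- cand[order(cost[cand], ig$ids[cand])]
    blocked <- integer()
    for (v in cand) {
      a2 <- alive; a2[v] <- FALSE
      f2 <- forb; f2[blocked] <- TRUE
      recurse(a2, f2, c(chosen, v), acc + cost[v])
      blocked <- c(blocked, v)
    }
    invisible()
  }

  recurse(rep(TRUE, ig$n), rep(FALSE, ig$n), integer(), 0)
  if (!is.finite(best$value)) stop("internal solver failed to find any FVS")
  list(members = best$members, value = best$value)
}

# Exact maximum-weight FVS of prescribed size s (any real weights). A node
# whose residual graph is acyclic is completed by padding with the
# highest-weight unused vertices (any superset of an FVS is an FVS); the
# bound is the same top-k relaxation without the acyclicity requirement.
# Returns NULL when no FVS of size exactly s exists (s below the minimum).
bb_max_weight_fixed_size <- function(ig, w, s) {
  best <- new.env(parent = emptyenv())
  best$value <- -Inf
  best$members <- integer()
  w_sorted_idx <- order(-w, ig$ids)

  top_fill <- function(chosen, k) {
    if (k == 0L) return(list(add = integer(), value = 0))
    pool <- setdiff(w_sorted_idx, chosen)
    if (length(pool) < k) return(NULL)
    add <- pool[seq_len(k)]
    list(add = add, value = sum(w[add]))
  }

  recurse <- function(alive, forb, chosen) {
    red <- ig_reduce(ig, alive, forb, chosen)
    if (is.null(red)) return(invisible())
    alive <- red$alive
    chosen <- red$chosen
    if (length(chosen) > s) return(invisible())
    ub_fill <- top_fill(chosen, s - length(chosen))
    if (is.null(ub_fill)) return(invisible())
    ub <- sum(w[chosen]) + ub_fill$value
    if (ub <= best$value) return(invisible())
    cyc <- ig_shortest_cycle(ig, alive)
    if (is.null(cyc)) {
      val <- sum(w[chosen]) + ub_fill$value
      if (val > best$value) {
        best$value <- val
        best$members <- sort(c(chosen, ub_fill$add))
      }
      return(invisible())
    }
    if (length(chosen) == s) return(invisible()) # cyclic but budget spent
    cand <- cyc[!forb[cyc]]
    if (length(cand) == 0L) return(invisible())
    cand <- cand[order(-w[cand], ig$ids[cand])]
    blocked <- integer()
    for (v in cand) {
      a2 <- alive; a2[v] <- FALSE
      f2 <- forb; f2[blocked] <- TRUE
      recurse(a2, f2, c(chosen, v))
      blocked <- c(blocked, v)
    }
    invisible()
  }

  recurse(rep(TRUE, ig$n), rep(FALSE, ig$n), integer())
  if (!is.finite(best$value)) return(NULL)
  list(members = best$members, value = best$value)
}
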
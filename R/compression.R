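#' Graph compression rules for feedback vertex set problems
#'
#' Feedback vertex set (FVS) instances from biological networks are large but
#' highly compressible. Three local rules, applied to a vertex `v`, shrink the
#' graph while preserving minimum feedback vertex sets (MFVSs):
#'
#' * **C1** — `v` has a self-loop: `v` lies in *every* FVS, so it is recorded
#'   as forced (delta-M) and removed ([rule_c1()]).
#' * **C2** — `v` has no successors or no predecessors: `v` lies on no cycle
#'   and in no MFVS, so it is removed ([rule_c2()]).
#' * **C3** — `v` has exactly one successor or exactly one predecessor `v'`:
#'   every cycle through `v` also passes `v'`, so breaking the cycle at `v'`
#'   is at least as good. [ignore_vertex()] rewires every predecessor of `v`
#'   to every successor (parallel arcs merge; a predecessor that is also a
#'   successor becomes a self-loop) and then removes `v`.
#'
#' C3 can discard *some* MFVSs, so for the weighted problem (find the
#' maximum-weight MFVS) the bypass is restricted: [ignore_w()] additionally
#' requires all weights to be strictly positive and the weight of `v` to be
#' strictly below the weight of its sole neighbour. An exchange argument then
#' guarantees `v` is in no maximum-weight MFVS, so no optimum is lost.
#'
#' Finally, arcs between different strongly connected components lie on no
#' cycle and can be deleted ([compress_scc()]).
#'
#' @param g a [wdigraph()].
#' @param v a vertex id satisfying the rule's precondition (otherwise an
#'   error).
#' @return `rule_c1()`: list with `graph` (the reduced graph) and `forced`
#'   (the vertex id, destined for delta-M). `rule_c2()`, `ignore_vertex()`,
#'   `ignore_w()`, `compress_scc()`: the reduced graph.
#' @seealso [compress_graph()] for the fixed-point driver.
#' @name compression_rules
NULL

#' @rdname compression_rules
#' @export
rule_c1 <- function(g, v) {
  if (!v %in% g$vertices) stop("vertex not in graph: ", v)
  if (!has_self_loop(g, v)) stop("rule C1 requires a self-loop at ", v)
  list(graph = remove_vertex(g, v), forced = v)
}

#' @rdname compression_rules
#' @export
rule_c2 <- function(g, v) {
  if (!v %in% g$vertices) stop("vertex not in graph: ", v)
  if (length(g$succ[[v]]) > 0L && length(g$pred[[v]]) > 0L) {
    stop("rule C2 requires empty successor or predecessor set at ", v)
  }
  remove_vertex(g, v)
}

#' @rdname compression_rules
#' @export
ignore_vertex <- function(g, v) {
  if (!v %in% g$vertices) stop("vertex not in graph: ", v)
  if (has_self_loop(g, v)) stop("ignore does not apply to self-loop vertex ", v)
  if (length(g$succ[[v]]) != 1L && length(g$pred[[v]]) != 1L) {
    stop("ignore requires a single successor or single predecessor at ", v)
  }
  preds <- g$pred[[v]]
  sucs <- g$succ[[v]]
  g <- remove_vertex(g, v)
  if (length(preds) > 0L && length(sucs) > 0L) {
    pairs <- expand.grid(p = preds, s = sucs, stringsAsFactors = FALSE)
    g <- add_arcs(g, pairs$p, pairs$s)
  }
  g
}

ignore_w_applicable <- function(g, v) {
  if (has_self_loop(g, v)) return(FALSE)
  (length(g$pred[[v]]) == 1L && g$w[[v]] < g$w[[g$pred[[v]]]]) ||
    (length(g$succ[[v]]) == 1L && g$w[[v]] < g$w[[g$succ[[v]]]])
}

#' @rdname compression_rules
#' @export
ignore_w <- function(g, v) {
  if (!v %in% g$vertices) stop("vertex not in graph: ", v)
  if (any(g$w <= 0)) {
    stop("ignore_w requires strictly positive weights (offending vertex: ",
         names(g$w)[which(g$w <= 0)[1L]], ")")
  }
  if (!ignore_w_applicable(g, v)) {
    stop("ignore_w not applicable at ", v,
         " (needs a single strictly heavier sole neighbour and no self-loop)")
  }
  ignore_vertex(g, v)
}

#' @rdname compression_rules
#' @export
compress_scc <- function(g) {
  blocks <- scc_partition(g)
  memb <- stats::setNames(rep(seq_along(blocks), lengths(blocks)),
                          unlist(blocks))
  for (v in g$vertices) {
    keep <- g$succ[[v]][memb[g$succ[[v]]] == memb[[v]]]
    drop <- setdiff(g$succ[[v]], keep)
    if (length(drop) > 0L) {
      g$succ[[v]] <- keep
      for (s in drop) g$pred[[s]] <- setdiff(g$pred[[s]], v)
    }
  }
  g
}

#' Compress a graph to its feedback-vertex-set core
#'
#' Applies the reduction rules C1, C2, C3 and SCC pruning (see
#' [compression_rules]) to a fixed point, in that priority order, scanning
#' vertices lexicographically. After every single C3 bypass the sweep restarts
#' so that any self-loop it creates is immediately harvested by C1. The fixed
#' point is reached when a full pass changes nothing.
#'
#' Modes select the C3 bypass:
#' * `"unweighted"` — [ignore_vertex()]; preserves the MFVS *size* (the union
#'   of delta-M and any MFVS of the compressed graph is an MFVS of the
#'   original graph).
#' * `"weighted"` — [ignore_w()]; additionally preserves the maximum-weight
#'   MFVS. Requires strictly positive weights.
#' * `"basic"` — no C3 at all (only C1, C2, SCC pruning), the always-safe
#'   reductions appropriate when the target is a weight-optimal FVS of
#'   unconstrained size.
#'
#' @param g a [wdigraph()].
#' @param mode one of `"unweighted"`, `"weighted"`, `"basic"`.
#' @return A `compression_trace`: list with `compressed` (the reduced
#'   [wdigraph()]), `delta_m` (sorted ids forced into every FVS), `steps`
#'   (data frame logging each rule application) and `mode`.
#' @examples
#' g <- wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' tr <- compress_graph(g, "unweighted")
#' tr$delta_m
#' @export
compress_graph <- function(g, mode = c("unweighted", "weighted", "basic")) {
  mode <- match.arg(mode)
  if (mode == "weighted" && any(g$w <= 0)) {
    stop("weighted compression requires strictly positive weights ",
         "(offending vertex: ", names(g$w)[which(g$w <= 0)[1L]], ")")
  }
  original <- g$vertices
  delta_m <- character()
  rules <- character()
  touched <- character()
  log_step <- function(rule, what) {
    rules <<- c(rules, rule)
    touched <<- c(touched, what)
  }

  repeat {
    changed <- FALSE
    # C1: harvest self-loops
    repeat {
      loops <- g$vertices[vapply(g$vertices, has_self_loop, TRUE, g = g)]
      if (length(loops) == 0L) break
      v <- loops[1L]
      st <- rule_c1(g, v)
      g <- st$graph
      delta_m <- c(delta_m, st$forced)
      log_step("C1", v)
      changed <- TRUE
    }
    # C2: strip vertices off every cycle
    repeat {
      deg0 <- g$vertices[lengths(g$succ) == 0L | lengths(g$pred) == 0L]
      if (length(deg0) == 0L) break
      g <- rule_c2(g, deg0[1L])
      log_step("C2", deg0[1L])
      changed <- TRUE
    }
    # C3 bypass: one application, then restart so C1 sees new self-loops
    if (mode != "basic") {
      elig <- if (mode == "unweighted") {
        g$vertices[vapply(g$vertices, function(v) {
          !has_self_loop(g, v) &&
            (length(g$succ[[v]]) == 1L || length(g$pred[[v]]) == 1L)
        }, TRUE)]
      } else {
        g$vertices[vapply(g$vertices, ignore_w_applicable, TRUE, g = g)]
      }
      if (length(elig) > 0L) {
        v <- elig[1L]
        g <- if (mode == "unweighted") ignore_vertex(g, v) else ignore_w(g, v)
        log_step(if (mode == "unweighted") "C3-ignore" else "C3-ignore_w", v)
        next
      }
    }
    # SCC pruning
    before <- n_arcs(g)
    g2 <- compress_scc(g)
    if (n_arcs(g2) < before) {
      g <- g2
      log_step("scc-prune", sprintf("%d arcs", before - n_arcs(g2)))
      changed <- TRUE
    }
    if (!changed) break
  }

  structure(
    list(compressed = g,
         delta_m = sort(delta_m),
         steps = data.frame(rule = rules, target = touched,
                            stringsAsFactors = FALSE),
         mode = mode,
         original_vertices = original),
    class = "compression_trace")
}

#' @export
print.compression_trace <- function(x, ...) {
  cat(sprintf(
    "<compression_trace> mode=%s: %d -> %d vertices, |delta_m| = %d, %d steps\n",
    x$mode, length(x$original_vertices), length(x$compressed$vertices),
    length(x$delta_m), nrow(x$steps)))
  invisible(x)
}

#' Lift a compressed-graph solution back to the original graph
#'
#' Any FVS of the compressed graph, united with the forced vertices delta-M,
#' is an FVS of the original graph (an MFVS under `"unweighted"` compression,
#' a maximum-weight MFVS under `"weighted"` compression when the solution was
#' optimal on the compressed graph).
#'
#' @param trace a `compression_trace` from [compress_graph()].
#' @param sol character vector of vertex ids, a subset of the compressed
#'   graph's vertices.
#' @return Sorted character vector `sol` united with `trace$delta_m`.
#' @export
lift_solution <- function(trace, sol) {
  stopifnot(inherits(trace, "compression_trace"))
  sol <- as.character(sol)
  bad <- setdiff(sol, trace$compressed$vertices)
  if (length(bad) > 0L) {
    stop("solution contains vertices not in the compressed graph: ", bad[1L])
  }
  sort(union(sol, trace$delta_m))
}
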
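#' Weighted directed graphs
#'
#' `wdigraph()` builds the vertex-weighted directed graph object every
#' algorithm in this package operates on: an opaque-string vertex set, a set
#' of arcs (ordered pairs; self-loops allowed; parallel arcs collapse), and
#' one real weight per vertex (0 when unassigned). Vertex ids are
#' case-sensitive and never normalised; iteration order is lexicographic by
#' id throughout the package so that runs are reproducible.
#'
#' Isolated vertices cannot be expressed by an edge list; supply them through
#' `vertices` (or later through a weight table).
#'
#' @param arcs two-column character matrix or data frame (from, to); `NULL`
#'   for an arcless graph.
#' @param vertices optional character vector of vertex ids to include in
#'   addition to the arc endpoints.
#' @param weights optional named numeric vector of vertex weights; vertices
#'   without an entry get weight 0.
#' @return An object of class `wdigraph` with fields `vertices` (sorted
#'   character vector), `succ` and `pred` (named lists of sorted successor /
#'   predecessor id vectors) and `w` (named numeric weights).
#' @examples
#' g <- wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' n_arcs(g)
#' @export
wdigraph <- function(arcs = NULL, vertices = NULL, weights = NULL) {
  if (is.null(arcs)) {
    am <- matrix(character(), ncol = 2L)
  } else {
    am <- as.matrix(arcs)
    if (ncol(am) < 2L) stop("arcs must have two columns (from, to)")
    am <- am[, 1:2, drop = FALSE]
    storage.mode(am) <- "character"
  }
  if (nrow(am) > 0L) {
    am <- am[!duplicated(paste0(am[, 1L], "\r", am[, 2L])), , drop = FALSE]
  }
  verts <- sort(unique(c(as.character(vertices), am[, 1L], am[, 2L])))
  succ <- pred <- stats::setNames(rep(list(character()), length(verts)), verts)
  if (nrow(am) > 0L) {
    sp <- split(am[, 2L], factor(am[, 1L], levels = verts))
    succ[names(sp)] <- lapply(sp, function(x) sort(unique(x)))
    pp <- split(am[, 1L], factor(am[, 2L], levels = verts))
    pred[names(pp)] <- lapply(pp, function(x) sort(unique(x)))
  }
  w <- stats::setNames(numeric(length(verts)), verts)
  if (!is.null(weights)) {
    hit <- intersect(names(weights), verts)
    w[hit] <- as.numeric(weights[hit])
  }
  structure(list(vertices = verts, succ = succ, pred = pred, w = w),
            class = "wdigraph")
}

#' @export
print.wdigraph <- function(x, ...) {
  cat(sprintf("<wdigraph> %d vertices, %d arcs\n",
              length(x$vertices), n_arcs(x)))
  invisible(x)
}

#' Number of vertices / arcs
#' @param g a `wdigraph`.
#' @return Integer count.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_arcs <- function(g) sum(lengths(g$succ))

#' Arc matrix of a graph
#'
#' @param g a `wdigraph`.
#' @return Two-column character matrix (`from`, `to`), rows ordered
#'   lexicographically by source then target.
#' @export
arc_matrix <- function(g) {
  from <- rep(g$vertices, lengths(g$succ))
  to <- unlist(g$succ, use.names = FALSE)
  if (is.null(to)) to <- character()
  cbind(from = from, to = to)
}

as_igraph <- function(g) {
  am <- arc_matrix(g)
  igraph::graph_from_data_frame(
    data.frame(from = am[, 1L], to = am[, 2L], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
}

#' Read / write a directed edge list
#'
#' The edge-list format is one arc per line, source then target, separated by
#' tabs or any whitespace. Lines starting with `#` are skipped, as is an
#' optional header line (`from/to`, `source/target`, case-insensitive).
#' Duplicate arc lines collapse to a single arc. An empty file yields the
#' empty graph.
#'
#' @param path file path.
#' @return `read_edge_list()`: a `wdigraph` with all weights 0;
#'   `write_edge_list()`: the path, invisibly.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(wdigraph())
  toks <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d: %s",
                 keep[bad[1L]], lines[keep[bad[1L]]]))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  hdr <- c("from", "source", "src", "tail")
  if (tolower(from[1L]) %in% hdr && length(from) > 1L) {
    from <- from[-1L]; to <- to[-1L]
  }
  wdigraph(cbind(from, to))
}

#' @rdname read_edge_list
#' @param g a `wdigraph`.
#' @export
write_edge_list <- function(g, path) {
  am <- arc_matrix(g)
  utils::write.table(am, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach vertex weights to a graph
#'
#' Every graph vertex found in the weight table receives its weight; vertices
#' without an entry get the default weight 0 and are recorded in the
#' `"defaulted"` attribute of the result (mirroring how genes absent from the
#' expression data keep a place in the network rather than being dropped).
#' Table entries whose ids are not graph vertices are ignored with a message.
#' Graph topology is never changed.
#'
#' @param g a `wdigraph`.
#' @param w a [weight_table()] (or named numeric vector).
#' @return `g` with weights replaced; `attr(, "defaulted")` lists the vertex
#'   ids that fell back to 0.
#' @export
apply_weights <- function(g, w) {
  entries <- if (inherits(w, "weight_table")) w$entries else w
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  extra <- setdiff(names(entries), g$vertices)
  if (length(extra) > 0L) {
    message(length(extra), " weight entries not in the graph were ignored")
  }
  hit <- intersect(g$vertices, names(entries))
  g$w[] <- 0
  g$w[hit] <- as.numeric(entries[hit])
  attr(g, "defaulted") <- setdiff(g$vertices, hit)
  g
}

#' Acyclicity test
#'
#' @param g a `wdigraph`.
#' @return `TRUE` iff `g` has no directed cycle; a self-loop counts as a
#'   cycle.
#' @export
is_acyclic <- function(g) {
  if (n_arcs(g) == 0L) return(TRUE)
  igraph::is_dag(as_igraph(g))
}

#' Strongly connected components
#'
#' @param g a `wdigraph`.
#' @return The unique partition of the vertex set into maximal strongly
#'   connected components: a list of sorted character vectors, ordered by
#'   their first element.
#' @export
scc_partition <- function(g) {
  if (n_vertices(g) == 0L) return(list())
  memb <- igraph::components(as_igraph(g), mode = "strong")$membership
  blocks <- split(names(memb), memb)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, `[[`, "", 1L))])
}

#' Remove vertices and their incident arcs
#'
#' @param g a `wdigraph`.
#' @param v vertex id(s) to remove; all must be present.
#' @return A new `wdigraph` without `v` and without any arc touching `v`; the
#'   input is not modified.
#' @export
remove_vertex <- function(g, v) {
  v <- as.character(v)
  miss <- setdiff(v, g$vertices)
  if (length(miss) > 0L) stop("vertex not in graph: ", miss[1L])
  keep <- setdiff(g$vertices, v)
  g$vertices <- keep
  g$succ <- lapply(g$succ[keep], setdiff, y = v)
  g$pred <- lapply(g$pred[keep], setdiff, y = v)
  g$w <- g$w[keep]
  g
}

add_arcs <- function(g, from, to) {
  # internal: endpoints must already be vertices
  for (i in seq_along(from)) {
    p <- from[i]; s <- to[i]
    if (!s %in% g$succ[[p]]) {
      g$succ[[p]] <- sort(c(g$succ[[p]], s))
      g$pred[[s]] <- sort(c(g$pred[[s]], p))
    }
  }
  g
}

has_self_loop <- function(g, v) v %in% g$succ[[v]]

#' Weight tables
#'
#' A weight table maps vertex ids to real weights and remembers which ids
#' received the default weight 0 because no data were available for them
#' (`defaulted`).
#'
#' @param entries named numeric vector of weights.
#' @param defaulted character vector of ids whose weight is a data-free
#'   default; must be a subset of `names(entries)` with weight 0.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(entries, defaulted = character()) {
  stopifnot(is.numeric(entries), !is.null(names(entries)) || length(entries) == 0L)
  entries <- entries[order(names(entries))]
  defaulted <- sort(as.character(defaulted))
  if (!all(defaulted %in% names(entries))) {
    stop("defaulted ids must be entries of the table")
  }
  if (length(defaulted) > 0L && any(entries[defaulted] != 0)) {
    stop("defaulted entries must have weight 0")
  }
  structure(list(entries = entries, defaulted = defaulted),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d entries (%d defaulted to 0)\n",
              length(x$entries), length(x$defaulted)))
  invisible(x)
}

#' Read / write a two-column weight table
#'
#' TSV with columns (vertex id, weight); `#` comments and an optional header
#' row are tolerated.
#'
#' @param path file path.
#' @return `read_weight_table()`: a [weight_table()];
#'   `write_weight_table()`: the path, invisibly.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(weight_table(stats::setNames(numeric(), character())))
  toks <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed weight table line %d", keep[bad[1L]]))
  }
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- vapply(toks, `[[`, "", 2L)
  if (is.na(suppressWarnings(as.numeric(vals[1L]))) && length(ids) > 1L) {
    ids <- ids[-1L]; vals <- vals[-1L]
  }
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) stop("non-numeric weight at line ", keep[which(is.na(num))[1L]])
  weight_table(stats::setNames(num, ids))
}

#' @rdname read_weight_table
#' @param w a [weight_table()].
#' @export
write_weight_table <- function(w, path) {
  utils::write.table(
    data.frame(id = names(w$entries), weight = unname(w$entries)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a plain vertex list (one id per line)
#'
#' Used for forced-vertex sets (delta-M) and gene sets.
#'
#' @param path file path.
#' @return `read_vertex_list()`: sorted character vector of unique ids;
#'   `write_vertex_list()`: the path, invisibly.
#' @export
read_vertex_list <- function(path) {
  if (!file.exists(path)) stop("vertex list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  sort(unique(lines[!grepl("^(#|$)", lines)]))
}

#' @rdname read_vertex_list
#' @param ids character vector of vertex ids.
#' @export
write_vertex_list <- function(ids, path) {
  writeLines(sort(unique(as.character(ids))), path)
  invisible(path)
}
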
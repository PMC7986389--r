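#' Reference gene sets restricted to a network
#'
#' Cancer-gene reference sets are compared with predictions only on their
#' *common genes*: the members that also occur in the network. Recall uses
#' the common set as its denominator.
#'
#' @param name set label.
#' @param members character vector of gene ids.
#' @param network_vertices character vector of network vertex ids.
#' @return An object of class `gene_set`: `name`, `members`, `common`.
#' @export
gene_set <- function(name, members, network_vertices) {
  members <- sort(unique(as.character(members)))
  structure(list(name = as.character(name),
                 members = members,
                 common = intersect(members, sort(network_vertices))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members, %d in network\n",
              x$name, length(x$members), length(x$common)))
  invisible(x)
}

#' @rdname gene_set
#' @param path one-gene-id-per-line text file; the file name (without
#'   extension) becomes the set name.
#' @export
read_gene_set <- function(path, network_vertices) {
  gene_set(sub("\\.[^.]*$", "", basename(path)),
           read_vertex_list(path), network_vertices)
}

#' Recall and precision on the common genes
#'
#' @param predicted character vector of predicted gene ids (network
#'   vertices).
#' @param gs a [gene_set()].
#' @return Named numeric: `recall` = hits / |common|, `precision` = hits /
#'   |predicted|; `NA` when the respective denominator is empty.
#' @export
recall_precision <- function(predicted, gs) {
  stopifnot(inherits(gs, "gene_set"))
  predicted <- unique(as.character(predicted))
  hits <- length(intersect(predicted, gs$common))
  c(recall = if (length(gs$common) == 0L) NA_real_ else hits / length(gs$common),
    precision = if (length(predicted) == 0L) NA_real_ else hits / length(predicted))
}

#' Null ensemble of MFVSs from shuffled weights
#'
#' Draws the permutation null used to judge an observed recall: the multiset
#' of vertex weights is randomly permuted over the vertices (defaulted zeros
#' included), the maximum-weight-MFVS pipeline is run on the shuffled
#' weights, and the output is kept only if it verifies as an FVS of the
#' original graph with exactly the minimum FVS size. Rejected replicates are
#' counted (`attempted` vs `approved`). Reproducible for a fixed seed.
#'
#' @param g a [wdigraph()].
#' @param w a [weight_table()] with strictly positive weights covering `g`.
#' @param count number of replicates to attempt (>= 1).
#' @param seed integer RNG seed.
#' @return List of class `mfvs_ensemble`: `solutions` (list of verified
#'   `fvs_solution`s), `attempted`, `approved`, `mfvs_size`.
#' @export
random_mfvs_ensemble <- function(g, w, count, seed) {
  stopifnot(count >= 1)
  entries <- if (inherits(w, "weight_table")) w$entries else w
  g <- apply_weights(g, entries)
  mfvs_size <- fvs_pipeline(g, method = "MFVS")$size
  ids <- g$vertices
  vals <- unname(g$w[ids])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sols <- list()
  approved <- 0L
  for (i in seq_len(count)) {
    shuffled <- stats::setNames(sample(vals), ids)
    sol <- tryCatch(fvs_pipeline(g, w = shuffled, method = "WMFVS"),
                    error = function(e) NULL)
    if (!is.null(sol) && isTRUE(verify_fvs(g, sol$members)) &&
        sol$size == mfvs_size) {
      # report weights under the original (unshuffled) table
      sol$total_weight <- sum(entries[sol$members])
      sol$objective_value <- sol$total_weight
      approved <- approved + 1L
      sols[[approved]] <- sol
    }
  }
  structure(list(solutions = sols, attempted = as.integer(count),
                 approved = approved, mfvs_size = mfvs_size),
            class = "mfvs_ensemble")
}

#' @export
print.mfvs_ensemble <- function(x, ...) {
  cat(sprintf("<mfvs_ensemble> %d approved of %d attempted (MFVS size %d)\n",
              x$approved, x$attempted, x$mfvs_size))
  invisible(x)
}

#' Empirical p-value against a permutation null
#'
#' Fraction of null recalls at least as large as the observed one:
#' `|{R in r_random : R >= r_obs}| / |r_random|`. Exact zeros are possible
#' when the observation exceeds the whole null.
#'
#' @param r_obs observed statistic (e.g. a recall).
#' @param r_random non-empty numeric vector of null statistics.
#' @return Empirical p-value in `[0, 1]`.
#' @export
empirical_p <- function(r_obs, r_random) {
  stopifnot(length(r_random) > 0L)
  mean(r_random >= r_obs)
}

#' Balanced running-sum enrichment score
#'
#' Walks a weight-ranked gene list and accumulates `+1/h` on members of the
#' gene set's common genes (`h` hits in the list) and `-1/(N - h)` on
#' non-members, so the running sum returns to 0 at the end of the list. The
#' enrichment score is the signed maximum-magnitude deviation of the curve:
#' large positive when the set concentrates at the top of the ranking.
#'
#' @param ranked character vector: all gene ids ordered by weight descending
#'   (ties broken lexicographically; see [rank_by_weight()]).
#' @param gs a [gene_set()] whose common genes are a non-empty strict subset
#'   of `ranked`.
#' @return List with `curve` (length `length(ranked)`, last element 0 within
#'   numerical tolerance) and `es`.
#' @export
enrichment_score <- function(ranked, gs) {
  stopifnot(inherits(gs, "gene_set"))
  n <- length(ranked)
  hit <- ranked %in% gs$common
  h <- sum(hit)
  if (h == 0L || h == n) {
    stop("enrichment score is degenerate when the set covers none or all of the ranking")
  }
  steps <- ifelse(hit, 1 / h, -1 / (n - h))
  curve <- cumsum(steps)
  es <- curve[which.max(abs(curve))]
  list(curve = curve, es = es)
}

#' Rank vertices by weight (descending)
#'
#' @param w a [weight_table()] or named numeric vector.
#' @return Character vector of ids, heaviest first; ties broken
#'   lexicographically by id.
#' @export
rank_by_weight <- function(w) {
  entries <- if (inherits(w, "weight_table")) w$entries else w
  names(entries)[order(-entries, names(entries))]
}

#' Dark / non-dark split of predicted cancer genes
#'
#' Among the predicted genes that are also reference cancer genes in the
#' network (`predicted` intersected with the set's common genes), the *dark*
#' genes are those missed by differential expression (not in the DEG set);
#' the rest are non-dark.
#'
#' @param predicted character vector of predicted gene ids.
#' @param gs a [gene_set()].
#' @param deg character vector of DEG ids (see [deg_call()]).
#' @return Named integer vector `c(dark = , non_dark = )`.
#' @export
dark_gene_split <- function(predicted, gs, deg) {
  stopifnot(inherits(gs, "gene_set"))
  hits <- intersect(unique(as.character(predicted)), gs$common)
  nd <- sum(hits %in% deg)
  c(dark = length(hits) - nd, non_dark = nd)
}

#' Genes recurring across an MFVS ensemble
#'
#' @param ensemble an `mfvs_ensemble` (or plain list of `fvs_solution`s).
#' @param fraction minimum fraction of ensemble members a gene must appear
#'   in, in `(0, 1]`.
#' @return Sorted character vector of recurring gene ids.
#' @export
frequency_gene_set <- function(ensemble, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  sols <- if (inherits(ensemble, "mfvs_ensemble")) ensemble$solutions else ensemble
  if (length(sols) == 0L) stop("empty ensemble")
  counts <- table(unlist(lapply(sols, function(s) s$members)))
  sort(names(counts)[counts >= fraction * length(sols)])
}

#' Top-k vertices by weight
#'
#' @param w a [weight_table()] or named numeric vector.
#' @param k number of vertices, `1 <= k <= length(w)`.
#' @return Character vector of the `k` heaviest ids; a tie at the boundary
#'   is broken lexicographically with a warning.
#' @export
top_k_by_weight <- function(w, k) {
  entries <- if (inherits(w, "weight_table")) w$entries else w
  if (k < 1 || k > length(entries)) stop("k must be in 1..", length(entries))
  ranked <- rank_by_weight(entries)
  if (k < length(entries) && entries[[ranked[k]]] == entries[[ranked[k + 1L]]]) {
    warning("weight tie at the k-boundary broken lexicographically")
  }
  ranked[seq_len(k)]
}

#' Evaluate an FVS prediction against reference gene sets
#'
#' Bundles the per-set metrics: recall/precision on common genes, empirical
#' p-value of the recall against a shuffled-weight MFVS ensemble, the
#' enrichment score of each set along the weight ranking, and the dark-gene
#' split of the prediction.
#'
#' @param predicted character vector of predicted gene ids.
#' @param gene_sets list of [gene_set()]s.
#' @param w a [weight_table()] (for the ranking).
#' @param ensemble optional `mfvs_ensemble` for p-values.
#' @param deg optional character vector of DEG ids for the dark-gene split.
#' @return An `eval_report`: per-set data frame plus the enrichment curves.
#' @export
evaluate_prediction <- function(predicted, gene_sets, w, ensemble = NULL,
                                deg = NULL) {
  ranked <- rank_by_weight(w)
  rows <- lapply(gene_sets, function(gs) {
    rp <- recall_precision(predicted, gs)
    p <- NA_real_
    if (!is.null(ensemble) && length(ensemble$solutions) > 0L) {
      null_recalls <- vapply(ensemble$solutions, function(s)
        recall_precision(s$members, gs)[["recall"]], numeric(1))
      p <- empirical_p(rp[["recall"]], null_recalls)
    }
    es <- tryCatch(enrichment_score(ranked, gs)$es, error = function(e) NA_real_)
    dk <- if (is.null(deg)) c(dark = NA_integer_, non_dark = NA_integer_)
          else dark_gene_split(predicted, gs, deg)
    data.frame(set = gs$name, common = length(gs$common),
               recall = rp[["recall"]], precision = rp[["precision"]],
               p_value = p, es = es,
               dark = dk[["dark"]], non_dark = dk[["non_dark"]],
               stringsAsFactors = FALSE)
  })
  curves <- lapply(gene_sets, function(gs)
    tryCatch(enrichment_score(ranked, gs)$curve, error = function(e) NULL))
  names(curves) <- vapply(gene_sets, function(gs) gs$name, "")
  structure(list(metrics = do.call(rbind, rows), es_curves = curves),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
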
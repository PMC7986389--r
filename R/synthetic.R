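#' Random directed graphs with planted cycles
#'
#' Generates sparse Erdos-Renyi-style digraphs whose feedback vertex set is
#' guaranteed non-trivial by planting directed cycles, emulating the cyclic
#' core of directed biological interaction networks at test scale. Cycles
#' are planted on disjoint consecutive vertex runs while vertices last (so
#' the expected minimum FVS size is controllable), then on random vertices.
#' Background arcs are added independently with probability `p` (no
#' self-loops). Generation is a pure function of the arguments: the same
#' spec always yields the identical graph.
#'
#' @param n number of vertices (labelled `v01`, `v02`, ...).
#' @param p background arc probability over ordered pairs, in `[0, 1]`.
#' @param n_cycles number of planted cycles.
#' @param cycle_len length of each planted cycle (>= 2, <= n).
#' @param weight_dist vertex weight distribution: `"uniform"` on
#'   `(weight_range[1], weight_range[2])`, `"lognormal"` with meanlog
#'   `weight_meanlog` and sdlog `weight_sdlog`, or `"constant"` (all 1).
#' @param weight_range,weight_meanlog,weight_sdlog distribution parameters.
#' @param seed integer RNG seed.
#' @return A [wdigraph()] with weights drawn per the spec.
#' @examples
#' g <- random_digraph(8, p = 0.1, n_cycles = 2, seed = 1)
#' is_acyclic(g)
#' @export
random_digraph <- function(n, p = 0.1, n_cycles = 1, cycle_len = 3,
                           weight_dist = c("uniform", "lognormal", "constant"),
                           weight_range = c(0.1, 3),
                           weight_meanlog = 0, weight_sdlog = 0.5,
                           seed = 1) {
  weight_dist <- match.arg(weight_dist)
  stopifnot(n >= 1, p >= 0, p <= 1, n_cycles >= 0)
  if (n_cycles > 0 && (cycle_len > n || cycle_len < 2)) {
    stop("planted cycles need 2 <= cycle_len <= n")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  ids <- sprintf("v%0*d", max(2L, nchar(n)), seq_len(n))
  from <- character(); to <- character()
  used <- 0L
  for (ci in seq_len(n_cycles)) {
    if (used + cycle_len <= n) {
      run <- ids[(used + 1L):(used + cycle_len)]
      used <- used + cycle_len
    } else {
      run <- sample(ids, cycle_len)
    }
    from <- c(from, run)
    to <- c(to, c(run[-1L], run[1L]))
  }
  if (p > 0) {
    pairs <- expand.grid(f = ids, t = ids, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$f != pairs$t, ]
    draw <- stats::runif(nrow(pairs)) < p
    from <- c(from, pairs$f[draw])
    to <- c(to, pairs$t[draw])
  }
  w <- switch(weight_dist,
              uniform = stats::runif(n, weight_range[1L], weight_range[2L]),
              lognormal = stats::rlnorm(n, weight_meanlog, weight_sdlog),
              constant = rep(1, n))
  arcs <- if (length(from) > 0L) cbind(from, to) else NULL
  wdigraph(arcs, vertices = ids, weights = stats::setNames(w, ids))
}

#' Simulate a tumour/normal expression matrix with planted effects
#'
#' Log2 expression of gene `g` in sample `j` is
#' `baseline_g + effect_g * [j is tumour] + Normal(0, noise_sd)`, then
#' exponentiated to the positive count-like scale. Recovered fold-change
#' weights should approach `|effect_g|` as sample counts grow. Deterministic
#' per seed.
#'
#' @param n_genes number of genes (ids `g001`, ...). Ignored when
#'   `effect_sizes` is a named vector covering the genes.
#' @param n_tumour,n_normal sample counts (>= 1 each).
#' @param effect_sizes named numeric vector of signed log2 shifts (tumour
#'   relative to normal); genes not named get effect 0. An unnamed scalar
#'   recycles to all genes.
#' @param noise_sd per-sample Gaussian noise on the log2 scale (> 0).
#' @param baseline_range log2 baseline drawn uniformly per gene.
#' @param seed integer RNG seed.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(n_genes, n_tumour, n_normal,
                                effect_sizes = 0, noise_sd = 0.5,
                                baseline_range = c(5, 9), seed = 1) {
  stopifnot(n_genes >= 1, n_tumour >= 1, n_normal >= 1, noise_sd > 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  genes <- if (!is.null(names(effect_sizes)) && length(effect_sizes) == n_genes) {
    names(effect_sizes)
  } else {
    sprintf("g%0*d", max(3L, nchar(n_genes)), seq_len(n_genes))
  }
  eff <- stats::setNames(numeric(n_genes), genes)
  if (is.null(names(effect_sizes))) {
    eff[] <- effect_sizes
  } else {
    hit <- intersect(names(effect_sizes), genes)
    eff[hit] <- effect_sizes[hit]
  }
  samples <- c(sprintf("T%03d", seq_len(n_tumour)),
               sprintf("N%03d", seq_len(n_normal)))
  labels <- stats::setNames(rep(c("tumour", "normal"), c(n_tumour, n_normal)),
                            samples)
  baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
  log2x <- matrix(baseline, n_genes, length(samples)) +
    outer(eff, as.numeric(labels == "tumour")) +
    matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
           n_genes, length(samples))
  values <- 2^log2x
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, labels)
}

#' Exhaustive feedback-vertex-set oracles
#'
#' Ground-truth solvers by subset enumeration, used to validate the
#' branch-and-bound and the compression rules on small instances. Both stop
#' with an error above `cap` vertices rather than silently truncating.
#'
#' `brute_force_all_mfvs()` enumerates subsets in increasing size and
#' returns the minimum FVS size together with *all* FVSs of that size.
#' `brute_force_wfvs()` scans every subset and returns the optimum over all
#' FVSs of any size: maximum total value (`"max_weight"`) or minimum total
#' value (`"min_penalty"`).
#'
#' @param g a [wdigraph()].
#' @param cap enumeration cap on the vertex count (default 15).
#' @return `brute_force_all_mfvs()`: list with `size` and `catalogue` (list
#'   of sorted id vectors). `brute_force_wfvs()`: list with `best` (sorted
#'   id vector) and `value`.
#' @examples
#' g <- wdigraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' brute_force_all_mfvs(g)$catalogue
#' @name fvs_oracle
#' @export
brute_force_all_mfvs <- function(g, cap = 15) {
  n <- n_vertices(g)
  if (n > cap) stop("oracle cap exceeded: ", n, " > ", cap)
  ig <- int_graph(g)
  all_alive <- rep(TRUE, max(n, 1L))
  if (n == 0L || ig_acyclic(ig, rep(TRUE, n))) {
    return(list(size = 0L, catalogue = list(character())))
  }
  for (s in seq_len(n)) {
    hits <- list()
    combos <- utils::combn(n, s)
    for (ci in seq_len(ncol(combos))) {
      alive <- rep(TRUE, n)
      alive[combos[, ci]] <- FALSE
      if (ig_acyclic(ig, alive)) {
        hits[[length(hits) + 1L]] <- sort(ig$ids[combos[, ci]])
      }
    }
    if (length(hits) > 0L) return(list(size = s, catalogue = hits))
  }
  stop("unreachable: the full vertex set is always an FVS")
}

#' @rdname fvs_oracle
#' @param values named numeric vector over the vertices: weights for
#'   `"max_weight"`, penalties for `"min_penalty"` (defaults to the graph's
#'   stored weights).
#' @param objective `"max_weight"` or `"min_penalty"`.
#' @export
brute_force_wfvs <- function(g, values = NULL,
                             objective = c("max_weight", "min_penalty"),
                             cap = 15) {
  objective <- match.arg(objective)
  n <- n_vertices(g)
  if (n > cap) stop("oracle cap exceeded: ", n, " > ", cap)
  if (is.null(values)) values <- g$w
  values <- values[g$vertices]
  if (anyNA(values)) stop("values must cover every vertex")
  ig <- int_graph(g)
  best_val <- if (objective == "max_weight") -Inf else Inf
  best_set <- NULL
  for (mask in 0:(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    alive <- rep(TRUE, n)
    alive[members] <- FALSE
    if (n > 0L && !ig_acyclic(ig, alive)) next
    val <- sum(values[members])
    better <- if (objective == "max_weight") val > best_val else val < best_val
    if (better) {
      best_val <- val
      best_set <- sort(ig$ids[members])
    }
  }
  list(best = best_set, value = best_val)
}
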
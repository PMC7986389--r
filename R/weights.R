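#' Expression matrices with tumour/normal labels
#'
#' Container for a genes-by-samples matrix of non-negative expression values
#' plus a sample label map partitioning the columns into `"tumour"` and
#' `"normal"`.
#'
#' @param values numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required), entries finite and `>= 0`.
#' @param labels named character vector mapping every sample id to
#'   `"tumour"` or `"normal"`; at least one of each.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative")
  }
  labels <- labels[colnames(values)]
  if (anyNA(labels) || !all(labels %in% c("tumour", "normal"))) {
    stop("every sample needs a label in {tumour, normal}")
  }
  if (!all(c("tumour", "normal") %in% labels)) {
    stop("need at least one tumour and one normal sample")
  }
  structure(list(values = values, labels = labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d tumour, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "tumour"), sum(x$labels == "normal")))
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample (header row with sample ids); the label TSV has two columns
#' (sample id, `tumour`|`normal`).
#'
#' @param expr_path path to the expression TSV.
#' @param labels_path path to the label TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(expr_path, labels_path) {
  tab <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  lab <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  expression_matrix(values, stats::setNames(lab[[2L]], lab[[1L]]))
}

#' Absolute mean log2 fold-change weight
#'
#' The vertex weight of a gene is the absolute difference between the mean
#' binary-log expression of the tumour samples and of the normal samples:
#' `| mean(log2 T) - mean(log2 N) |`. A high value flags strong differential
#' expression.
#'
#' @param tumour,normal non-empty numeric vectors of strictly positive
#'   expression values (add a pseudocount upstream if the data contain
#'   zeros; see [build_weight_table()]).
#' @return Non-negative real weight.
#' @examples
#' fc_weight(c(4, 4), c(1, 1)) # == 2
#' @export
fc_weight <- function(tumour, normal) {
  stopifnot(length(tumour) > 0L, length(normal) > 0L)
  if (any(tumour <= 0) || any(normal <= 0)) {
    stop("fc_weight needs strictly positive values; ",
         "apply a pseudocount before taking logs")
  }
  abs(mean(log2(tumour)) - mean(log2(normal)))
}

#' Derive a network weight table from expression data
#'
#' Every network vertex present in the expression matrix gets its
#' [fc_weight()] (computed on `value + pseudocount`); vertices without
#' expression data get the default weight 0 and are recorded as `defaulted`
#' rather than being dropped, so that topologically essential genes with
#' missing data can still be selected. Genes in the matrix that are not
#' network vertices are dropped. Network topology is untouched.
#'
#' @param x an [expression_matrix()].
#' @param network_vertices character vector of network vertex ids.
#' @param pseudocount non-negative constant added to every expression value
#'   before the log (default 1; use 0 only when all values are strictly
#'   positive).
#' @return A [weight_table()] covering exactly `network_vertices`.
#' @export
build_weight_table <- function(x, network_vertices, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"), pseudocount >= 0)
  network_vertices <- sort(unique(as.character(network_vertices)))
  tum <- x$labels == "tumour"
  vals <- x$values + pseudocount
  covered <- intersect(network_vertices, rownames(x$values))
  w <- stats::setNames(numeric(length(network_vertices)), network_vertices)
  for (gene in covered) {
    w[gene] <- fc_weight(vals[gene, tum], vals[gene, !tum])
  }
  weight_table(w, defaulted = setdiff(network_vertices, covered))
}

#' Differentially-expressed-gene call
#'
#' A gene is a DEG when its absolute log2 fold change is at least
#' `fc_threshold` and its (externally supplied) adjusted p-value is at most
#' `p_threshold`. The package computes no p-values itself; when `adj_p` is
#' absent the call rests on the fold change alone.
#'
#' @param weight absolute log2 fold change (the [fc_weight()] value).
#' @param fc_threshold fold-change threshold (default 1; inclusive `>=`).
#' @param adj_p optional adjusted p-value (`NA` when unavailable).
#' @param p_threshold p-value threshold (default 0.05; inclusive `<=`).
#' @return Logical (vectorised over `weight` and `adj_p`).
#' @export
deg_call <- function(weight, fc_threshold = 1, adj_p = NA_real_,
                     p_threshold = 0.05) {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  weight >= fc_threshold & (is.na(adj_p) | adj_p <= p_threshold)
}
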
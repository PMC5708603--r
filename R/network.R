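# Static weighted network container and its projection onto
# sample-specific transcriptomes.

#' Build a weighted network from an edge list
#'
#' @param edges an `edge_list` (see [read_edge_list()]).
#' @param nodes optional character vector of node symbols; defaults to
#'   the genes appearing in `edges`. Extra nodes are kept as isolated
#'   vertices.
#' @return a list of class `weighted_network` with elements `nodes`
#'   (ordered gene symbols), `adjacency` (symmetric sparse
#'   [Matrix::dgCMatrix-class] with zero diagonal) and `degree`
#'   (weighted degree vector).
#' @export
weighted_network <- function(edges, nodes = NULL) {
  stopifnot(inherits(edges, "edge_list"))
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  i <- match(edges$gene_a, nodes)
  j <- match(edges$gene_b, nodes)
  n <- length(nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2L),
                            dims = c(n, n), dimnames = list(nodes, nodes))
  structure(list(nodes = nodes,
                 adjacency = W,
                 degree = stats::setNames(Matrix::rowSums(W), nodes)),
            class = "weighted_network")
}

#' @exportS3Method base::print
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", length(x$nodes), "nodes,",
      Matrix::nnzero(x$adjacency) / 2, "edges\n")
  invisible(x)
}

n_components <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::count_components(g)
}

#' Expression threshold defining "expressed" genes
#'
#' For RNA-seq the threshold is the conventional 1 RPKM. For array
#' intensities, which are on an arbitrary scale, the threshold is
#' percentile-matched: the empirical percentile of 1 RPKM over all
#' entries of a reference RNA-seq matrix is computed, and the array
#' threshold is the value at that same percentile of the array matrix
#' (linear interpolation over all entries).
#'
#' @param matrix an `expression_matrix`.
#' @param reference a reference RNA-seq `expression_matrix`; required
#'   when `matrix$platform == "array"`.
#' @param rpkm_cutoff the RNA-seq expression cutoff (default 1 RPKM).
#' @return a scalar threshold with attribute `percentile` recording the
#'   matched percentile (arrays only).
#' @export
expression_threshold <- function(matrix, reference = NULL, rpkm_cutoff = 1) {
  stopifnot(inherits(matrix, "expression_matrix"),
            length(matrix$values) > 0L)
  if (matrix$platform == "rnaseq") return(rpkm_cutoff)
  if (is.null(reference) || reference$platform != "rnaseq") {
    stop("array threshold requires a reference RNA-seq expression matrix",
         call. = FALSE)
  }
  pct <- mean(reference$values < rpkm_cutoff)
  thr <- unname(stats::quantile(as.numeric(matrix$values), probs = pct,
                                type = 7, names = FALSE))
  attr(thr, "percentile") <- pct
  thr
}

#' Project a network onto one sample's transcriptome
#'
#' Keeps the subgraph induced by the genes expressed in the sample
#' (expression at or above `threshold`); a network gene that is absent
#' from the expression matrix is treated as unexpressed. Isolated
#' expressed genes are retained as zero-degree nodes.
#'
#' @param network a `weighted_network`.
#' @param matrix an `expression_matrix` containing `sample_id`.
#' @param sample_id column of `matrix` to project onto.
#' @param threshold expression cutoff; defaults to
#'   [expression_threshold()] of `matrix` (1 RPKM for RNA-seq).
#' @param count_components whether to run the (comparatively costly)
#'   connected-component count; the count is stored as `n_components`.
#' @return a list of class `sample_network`: `sample_id`, `nodes`
#'   (the expressed subset V_s), `adjacency` (induced W_s), `degree`,
#'   `n_components`, `parent_nodes`.
#' @export
project <- function(network, matrix, sample_id, threshold = NULL,
                    count_components = TRUE) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(matrix, "expression_matrix"))
  if (!sample_id %in% colnames(matrix$values)) {
    stop("sample '", sample_id, "' not in expression matrix", call. = FALSE)
  }
  threshold <- threshold %||% expression_threshold(matrix)
  expr <- matrix$values[, sample_id]
  expressed_genes <- rownames(matrix$values)[expr >= threshold]
  keep <- network$nodes %in% expressed_genes
  if (!any(keep)) {
    stop("no network gene expressed in sample '", sample_id, "'",
         call. = FALSE)
  }
  Ws <- network$adjacency[keep, keep, drop = FALSE]
  nodes <- network$nodes[keep]
  structure(list(sample_id = sample_id,
                 nodes = nodes,
                 adjacency = Ws,
                 degree = stats::setNames(Matrix::rowSums(Ws), nodes),
                 n_components = if (count_components) n_components(Ws) else NA_integer_,
                 parent_nodes = network$nodes),
            class = "sample_network")
}

#' @exportS3Method base::print
print.sample_network <- function(x, ...) {
  cat("sample_network '", x$sample_id, "': ", length(x$nodes), " nodes, ",
      Matrix::nnzero(x$adjacency) / 2, " edges, ",
      x$n_components, " components\n", sep = "")
  invisible(x)
}

#' Per-sample projection summary
#'
#' Node, edge and connected-component counts for every sample of an
#' expression matrix projected onto a network.
#'
#' @inheritParams project
#' @return data frame with one row per sample: `sample_id`,
#'   `condition`, `n_nodes`, `n_edges`, `n_components`.
#' @export
projection_summary <- function(network, matrix, threshold = NULL) {
  threshold <- threshold %||% expression_threshold(matrix)
  rows <- lapply(colnames(matrix$values), function(s) {
    sn <- project(network, matrix, s, threshold)
    data.frame(sample_id = s,
               condition = as.character(matrix$condition[[s]]),
               n_nodes = length(sn$nodes),
               n_edges = Matrix::nnzero(sn$adjacency) / 2,
               n_components = sn$n_components,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Boolean gene-by-sample "expressed" matrix over the network's node set.
expressed_matrix <- function(network, matrix, threshold = NULL) {
  threshold <- threshold %||% expression_threshold(matrix)
  genes <- network$nodes
  out <- matrix(FALSE, length(genes), ncol(matrix$values),
                dimnames = list(genes, colnames(matrix$values)))
  common <- intersect(genes, rownames(matrix$values))
  out[common, ] <- matrix$values[common, , drop = FALSE] >= threshold
  out
}
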
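# Function-catalog filters: which gene sets are analyzable at all.
# Three criteria: set size within [50, 500]; mean leave-one-out
# diffusion recall over the static network >= 0.1 (the set must obey
# guilt-by-association); and the set must be modestly expressed in a
# reasonable share of samples.

#' Size filter for gene sets
#'
#' @param collection a `gene_set_collection`.
#' @param min,max inclusive bounds on set size (defaults 50 and 500).
#' @return named logical vector of pass flags.
#' @export
size_filter <- function(collection, min = 50, max = 500) {
  n <- lengths(collection)
  stats::setNames(n >= min & n <= max, names(collection))
}

#' Leave-one-out diffusion recall of a gene set
#'
#' For each annotated gene present in the static network, the rest of
#' the set is used as seeds, scores are diffused and calibrated against
#' a random-seed null of the matching seed size, and the held-out gene
#' counts as recovered when it is assigned (p-value at or below
#' `p_threshold`, positive score). The recall is the recovered
#' fraction. Sets that cluster in the network recall well; scattered
#' sets recall at roughly the false-positive rate.
#'
#' @param network the static `weighted_network`.
#' @param annotated character vector `A_f`.
#' @param alpha restart weight.
#' @param n_boot,p_threshold null-calibration settings (defaults 100
#'   and 0.01, as in the per-sample pipeline).
#' @param rng_seed RNG seed for the null draws.
#' @param op optional prebuilt [diffusion_operator()] for `network`.
#' @return mean recall in `[0, 1]`.
#' @export
loo_recall <- function(network, annotated, alpha = 0.2, n_boot = 100,
                       p_threshold = 0.01, rng_seed = 1, op = NULL) {
  op <- op %||% diffusion_operator(network, alpha)
  nodes <- op$nodes
  members <- which(nodes %in% annotated)
  if (length(members) < 2L) {
    stop("leave-one-out recall needs >= 2 annotated genes in the network",
         call. = FALSE)
  }
  k <- length(members) - 1L
  null <- estimate_null(op, k, n_boot = n_boot, rng_seed = rng_seed)
  # one RHS per held-out gene: the set minus that gene
  n <- length(nodes)
  i <- unlist(lapply(seq_along(members), function(j) members[-j]))
  Y <- Matrix::sparseMatrix(i = i,
                            j = rep(seq_along(members), each = k),
                            x = 1, dims = c(n, length(members)))
  F <- op$solve(Y)
  recovered <- vapply(seq_along(members), function(j) {
    g <- members[j]
    p <- score_pvalue(F[g, j], null$mean[g], null$sd[g])
    (p <= p_threshold) && F[g, j] > 0
  }, TRUE)
  mean(recovered)
}

#' Expression-activity filter for gene sets
#'
#' A set passes when the fraction of its (measured) annotated genes
#' expressed in a sample reaches `frac` in at least `sample_frac` of
#' all samples (both comparisons inclusive).
#'
#' @param collection a `gene_set_collection`.
#' @param matrix an `expression_matrix`.
#' @param threshold expression cutoff; default [expression_threshold()].
#' @param frac required expressed fraction of annotated genes
#'   (default 0.85).
#' @param sample_frac required fraction of qualifying samples
#'   (default 0.20).
#' @return named logical vector of pass flags, with the per-function
#'   count of qualifying samples as attribute `n_qualifying`.
#' @export
expression_activity_filter <- function(collection, matrix, threshold = NULL,
                                       frac = 0.85, sample_frac = 0.20) {
  threshold <- threshold %||% expression_threshold(matrix)
  expressed <- matrix$values >= threshold
  n_samples <- ncol(expressed)
  qual <- vapply(collection, function(g) {
    g <- intersect(g, rownames(expressed))
    if (length(g) == 0L) return(0L)
    sum(colMeans(expressed[g, , drop = FALSE]) >= frac)
  }, 0L)
  flags <- qual >= sample_frac * n_samples
  attr(flags, "n_qualifying") <- qual
  flags
}

#' Apply all three function filters
#'
#' @inheritParams loo_recall
#' @param collection a `gene_set_collection`.
#' @param matrix an `expression_matrix` for the expression-activity
#'   criterion.
#' @param size_min,size_max set-size bounds.
#' @param recall_min leave-one-out recall cutoff (default 0.1).
#' @param frac,sample_frac expression-activity settings.
#' @param threshold expression cutoff.
#' @param global_seed seed for the recall nulls (one derived seed per
#'   function).
#' @return a `function_filter_report` data frame: `function_id`,
#'   `n_annotated`, `n_in_network`, `mean_loo_recall`,
#'   `n_active_samples`, the three pass flags and `pass_all`.
#' @export
filter_functions <- function(network, collection, matrix,
                             size_min = 50, size_max = 500,
                             recall_min = 0.1, frac = 0.85,
                             sample_frac = 0.20, threshold = NULL,
                             alpha = 0.2, n_boot = 100, p_threshold = 0.01,
                             global_seed = 1) {
  pass_size <- size_filter(collection, size_min, size_max)
  pass_expr <- expression_activity_filter(collection, matrix, threshold,
                                          frac, sample_frac)
  op <- diffusion_operator(network, alpha)
  recall <- vapply(names(collection), function(f) {
    members <- intersect(collection[[f]], network$nodes)
    if (length(members) < 2L) return(0)
    loo_recall(network, members, alpha, n_boot, p_threshold,
               rng_seed = derive_seed(global_seed, "loo", f), op = op)
  }, 0)
  out <- data.frame(
    function_id = names(collection),
    n_annotated = lengths(collection),
    n_in_network = vapply(collection,
                          function(g) sum(g %in% network$nodes), 0L),
    mean_loo_recall = recall,
    n_active_samples = attr(pass_expr, "n_qualifying"),
    pass_size = unname(pass_size),
    pass_recall = recall >= recall_min,
    pass_expression = as.vector(pass_expr),
    stringsAsFactors = FALSE)
  out$pass_all <- out$pass_size & out$pass_recall & out$pass_expression
  rownames(out) <- NULL
  class(out) <- c("function_filter_report", "data.frame")
  out
}
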
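# End-to-end per-sample assignment pipeline: project the network onto
# each sample, diffuse every function, calibrate against seed-size
# binned nulls, and collect the sparse gene x function x sample
# assignment tensor.

#' Assign functions to genes in every sample
#'
#' For each sample the interaction network is projected onto the
#' sample's transcriptome, every gene set is propagated from its
#' expressed annotated genes, and raw scores are calibrated against
#' random-seed nulls: functions are grouped into seed-size bins
#' (member seed sizes within `bin_tol` of the bin median) and one null
#' of `n_boot` random diffusions is estimated per bin. A gene is
#' assigned a function in a sample when its upper-tail normal p-value
#' is at most `p_threshold` and its raw score is positive.
#'
#' @param network a `weighted_network`.
#' @param matrix an `expression_matrix` with per-sample condition
#'   labels.
#' @param collection a `gene_set_collection` of functions to diffuse.
#' @param alpha restart weight (default 0.2).
#' @param n_boot null bootstrap draws per bin (default 100).
#' @param p_threshold assignment p-value cutoff (default 0.01,
#'   compared with `<=`).
#' @param threshold expression cutoff; default [expression_threshold()].
#' @param reference reference RNA-seq matrix for array percentile
#'   matching (see [expression_threshold()]).
#' @param bin_tol seed-size bin half-width (default 10).
#' @param global_seed integer seed; per-(sample, bin) RNG seeds are
#'   derived from it with [derive_seed()].
#' @param samples optional subset of sample IDs to process.
#' @param verbose print per-sample progress.
#' @return a list of class `assignment_result`:
#'   \describe{
#'     \item{assignments}{data frame `(gene, function_id, sample_id)` —
#'       the sparse boolean assignment tensor.}
#'     \item{expressed}{logical network-gene x sample matrix.}
#'     \item{condition}{named per-sample condition factor.}
#'     \item{seed_sizes}{function x sample matrix of seed sizes
#'       `|A_f` intersect `V_s|`.}
#'     \item{collection, p_threshold, alpha, threshold, n_boot,
#'       global_seed}{the calibrated configuration.}
#'   }
#' @export
assign_functions <- function(network, matrix, collection,
                             alpha = 0.2, n_boot = 100, p_threshold = 0.01,
                             threshold = NULL, reference = NULL,
                             bin_tol = 10, global_seed = 1,
                             samples = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(matrix, "expression_matrix"),
            inherits(collection, "gene_set_collection"))
  threshold <- threshold %||% expression_threshold(matrix, reference)
  samples <- samples %||% colnames(matrix$values)
  expressed <- expressed_matrix(network, matrix, threshold)
  fun_ids <- names(collection)
  seed_sizes <- base::matrix(0L, length(fun_ids), length(samples),
                             dimnames = list(fun_ids, samples))
  triples <- vector("list", length(samples))

  for (si in seq_along(samples)) {
    s <- samples[si]
    sn <- project(network, matrix, s, threshold, count_components = FALSE)
    op <- diffusion_operator(sn, alpha)
    n <- length(sn$nodes)

    seed_idx <- lapply(collection, function(g) which(sn$nodes %in% g))
    k <- lengths(seed_idx)
    seed_sizes[, si] <- as.integer(k)
    active <- fun_ids[k > 0]
    if (length(active) == 0L) next

    bins <- build_bins(stats::setNames(k[active], active), tol = bin_tol)
    nulls <- lapply(split(bins, bins$bin_id), function(b) {
      bs <- b$bin_seed_size[1]
      estimate_null(op, bs, n_boot = n_boot,
                    rng_seed = derive_seed(global_seed, s, bs))
    })
    bin_of <- stats::setNames(as.character(bins$bin_id), bins$function_id)

    Y <- Matrix::sparseMatrix(
      i = unlist(seed_idx[active]),
      j = rep(seq_along(active), k[active]),
      x = 1, dims = c(n, length(active)))
    F <- op$solve(Y)

    out <- lapply(seq_along(active), function(fi) {
      nb <- nulls[[bin_of[[active[fi]]]]]
      hit <- assign_from_null(F[, fi], nb, p_threshold)
      sn$nodes[hit]
    })
    n_hit <- lengths(out)
    if (sum(n_hit) > 0) {
      triples[[si]] <- data.frame(
        gene = unlist(out, use.names = FALSE),
        function_id = rep(active, n_hit),
        sample_id = s,
        stringsAsFactors = FALSE)
    }
    vlog(verbose, "sample ", s, ": |V_s| = ", n, ", ",
         max(bins$bin_id), " null bin(s), ", sum(n_hit), " assignments")
  }

  assignments <- do.call(rbind, triples[!vapply(triples, is.null, TRUE)])
  if (is.null(assignments)) {
    assignments <- data.frame(gene = character(), function_id = character(),
                              sample_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(assignments = assignments,
                 expressed = expressed[, samples, drop = FALSE],
                 condition = matrix$condition[samples],
                 seed_sizes = seed_sizes,
                 collection = collection,
                 p_threshold = p_threshold,
                 alpha = alpha,
                 threshold = threshold,
                 n_boot = n_boot,
                 global_seed = global_seed),
            class = "assignment_result")
}

#' @exportS3Method base::print
print.assignment_result <- function(x, ...) {
  cat("assignment_result: ", nrow(x$assignments), " assignments | ",
      nrow(x$seed_sizes), " functions x ", ncol(x$seed_sizes),
      " samples (p <= ", x$p_threshold, ")\n", sep = "")
  invisible(x)
}

#' Permute condition labels of an assignment result
#'
#' Sample-shuffling control: randomly reassigns the condition labels
#' across samples (assignments themselves are label-agnostic), so that
#' re-running the gain/loss stage measures the no-signal behaviour of
#' the downstream statistics.
#'
#' @param result an `assignment_result`.
#' @param rng_seed integer seed for the permutation.
#' @return the result with permuted `condition`.
#' @export
permute_conditions <- function(result, rng_seed = 1) {
  stopifnot(inherits(result, "assignment_result"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  perm <- sample(length(result$condition))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  result$condition <- stats::setNames(result$condition[perm],
                                      names(result$condition))
  result
}

#' Write the sparse assignment tensor as a 3-column TSV
#'
#' @param result an `assignment_result`.
#' @param path output path.
#' @export
write_assignments <- function(result, path) {
  utils::write.table(result$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
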
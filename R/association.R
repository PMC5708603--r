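# Downstream association statistics: elevated mutation/CNV labels for
# gained/lost gene sets, 2x2 class-enrichment Fisher tests, Spearman
# trends, permutation-calibrated driver AUC, activity profiles and
# feature selection.

#' One-sided elevated-statistic test for a gene set
#'
#' Wilcoxon rank-sum test of whether the event frequencies of a gene
#' set are elevated relative to the remaining genes
#' (alternative: set > rest).
#'
#' @param set_values frequencies of the gene set.
#' @param background_values frequencies of the rest of the genes.
#' @param p_cutoff flag threshold (default 0.05).
#' @param method `"auto"` (exact when the group sizes are small enough
#'   to enumerate, else normal approximation), `"exact"` or
#'   `"normal"`. The exact path is a tie-aware permutation p-value
#'   computed by dynamic programming over the rank-sum distribution.
#' @return list `(p, flag, n_set, n_background)`; an empty set returns
#'   `p = 1`, `flag = 0`.
#' @export
elevated_stat_test <- function(set_values, background_values, p_cutoff = 0.05,
                               method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(set_values) == 0L) {
    return(list(p = 1, flag = 0L, n_set = 0L,
                n_background = length(background_values)))
  }
  n <- length(set_values) + length(background_values)
  if (method == "auto") {
    method <- if (choose(n, length(set_values)) <= 2e4) "exact" else "normal"
  }
  p <- if (method == "exact") {
    rank_sum_exact_p(set_values, background_values)
  } else {
    suppressWarnings(
      stats::wilcox.test(set_values, background_values,
                         alternative = "greater", exact = FALSE)$p.value)
  }
  list(p = p, flag = as.integer(p <= p_cutoff),
       n_set = length(set_values), n_background = length(background_values))
}

# Exact one-sided (greater) permutation p-value of the rank sum,
# tie-aware: ranks are doubled to make average ranks integral and the
# subset-sum distribution is built by dynamic programming.
rank_sum_exact_p <- function(x, y) {
  r2 <- as.integer(round(2 * rank(c(x, y))))
  nx <- length(x)
  obs <- sum(r2[seq_len(nx)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank
  # sum s, over the items processed so far
  counts <- matrix(0, nx + 1, smax + 1)
  counts[1, 1] <- 1
  for (v in r2) {
    for (k in rev(seq_len(nx))) {
      src <- counts[k, ]
      hit <- which(src > 0)
      if (length(hit)) {
        dest <- hit + v
        dest_ok <- dest <= smax + 1
        counts[k + 1, dest[dest_ok]] <-
          counts[k + 1, dest[dest_ok]] + src[hit[dest_ok]]
      }
    }
  }
  tail_count <- sum(counts[nx + 1, (obs + 1):(smax + 1)])
  tail_count / choose(length(r2), nx)
}

#' Label functions with elevated mutation / deletion-CNV status
#'
#' For each function with a net gain, the missense-mutation frequency
#' of its gained (un-annotated) genes is compared against all other
#' genes; for each function with a net loss, the nonsense-mutation and
#' deletion-CNV frequencies of its lost genes are tested the same way.
#' `Mut(f) = 1` / `CNV(f) = 1` when the corresponding one-sided
#' Wilcoxon p-value is at most `p_cutoff`.
#'
#' @param deltas a `function_deltas` from [function_deltas()].
#' @param stats_table a `gene_stat_table` with columns
#'   `missense_freq`, `nonsense_freq`, `cnv_del_freq`.
#' @param p_cutoff label threshold (default 0.05).
#' @return data frame of class `function_labels`: `function_id`,
#'   `direction` (gain/loss/none by sign of `delta_f`), `mut_p`,
#'   `mut_flag`, `cnv_p`, `cnv_flag`.
#' @export
label_functions <- function(deltas, stats_table, p_cutoff = 0.05) {
  stopifnot(inherits(deltas, "function_deltas"),
            inherits(stats_table, "gene_stat_table"))
  all_genes <- rownames(stats_table)
  rows <- lapply(seq_len(nrow(deltas)), function(i) {
    f <- deltas$function_id[i]
    d <- deltas$delta_f[i]
    direction <- if (d > 0) "gain" else if (d < 0) "loss" else "none"
    genes <- if (d > 0) deltas$gained_genes[[i]] else deltas$lost_genes[[i]]
    genes <- intersect(genes, all_genes)
    rest <- setdiff(all_genes, genes)
    mut_col <- if (d > 0) "missense_freq" else "nonsense_freq"
    mut <- elevated_stat_test(stats_table[genes, mut_col],
                              stats_table[rest, mut_col], p_cutoff)
    cnv <- elevated_stat_test(stats_table[genes, "cnv_del_freq"],
                              stats_table[rest, "cnv_del_freq"], p_cutoff)
    data.frame(function_id = f, direction = direction,
               mut_p = mut$p, mut_flag = mut$flag,
               cnv_p = cnv$p, cnv_flag = cnv$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("function_labels", "data.frame")
  out
}

#' Class-enrichment odds ratio and Fisher test for a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` of the table
#' `rbind(c(a, b), c(c, d))` together with the two-sided Fisher exact
#' p-value.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return list `(odds_ratio, p)`.
#' @export
class_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  or <- odds_ratio_2x2(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2])
  list(odds_ratio = unname(or),
       p = unname(stats::fisher.test(counts)$p.value))
}

#' Spearman correlation between per-function net change and a statistic
#'
#' @param deltas numeric vector (e.g. `delta_f`).
#' @param statistic paired numeric vector.
#' @return Spearman rank correlation (average ranks for ties);
#'   incomplete pairs are dropped.
#' @export
delta_stat_correlation <- function(deltas, statistic) {
  keep <- is.finite(deltas) & is.finite(statistic)
  if (sum(keep) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  stats::cor(deltas[keep], statistic[keep], method = "spearman")
}

#' Per-gene tendency to gain or lose function
#'
#' Fraction of all evaluated functions called gained (respectively
#' lost) by each gene, over the un-annotated non-biased records.
#'
#' @param records a `gain_loss_records`.
#' @param genes gene universe to report (default: all genes appearing
#'   in the records).
#' @param n_functions number of evaluated functions (default: count of
#'   distinct functions in the records).
#' @return data frame `(gene, gain_tendency, loss_tendency)`.
#' @export
gene_tendency <- function(records, genes = NULL,
                          n_functions = length(unique(records$function_id))) {
  eligible <- records[!records$annotated & !records$biased, , drop = FALSE]
  genes <- genes %||% sort(unique(records$gene))
  gains <- table(factor(eligible$gene[eligible$call == "gain"], levels = genes))
  losses <- table(factor(eligible$gene[eligible$call == "loss"], levels = genes))
  data.frame(gene = genes,
             gain_tendency = as.numeric(gains) / n_functions,
             loss_tendency = as.numeric(losses) / n_functions,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-based AUC with a label-permutation null
#'
#' AUC of a score (e.g. gain tendency) for separating a positive gene
#' set from the rest, computed from ranks with half-credit for ties,
#' plus an empirical p-value from `n_perm` random relabelings using
#' add-one smoothing: `p = (1 + #{perm AUC >= observed}) / (n_perm + 1)`.
#'
#' @param scores named numeric vector over the gene universe.
#' @param positive_set character vector of positive genes (must be a
#'   nonempty strict subset of `names(scores)`).
#' @param n_perm number of label permutations (default 2000).
#' @param rng_seed RNG seed for the permutations.
#' @return list `(auc, p, n_perm)`.
#' @export
driver_auc <- function(scores, positive_set, n_perm = 2000, rng_seed = 1) {
  genes <- names(scores)
  stopifnot(!is.null(genes))
  pos <- genes %in% positive_set
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("positive set must be a nonempty strict subset of the universe",
         call. = FALSE)
  }
  r <- rank(scores)   # average ranks handle ties as half credit
  auc_of <- function(p) (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  obs <- auc_of(pos)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    auc_of(seq_along(r) %in% sample.int(length(r), n1))
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(auc = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1), n_perm = n_perm)
}

#' Per-sample functional activity profiles
#'
#' `x_diffusion[s, f]` counts the genes assigned function `f` in sample
#' `s` by diffusion; `x_annotation[s, f]` counts the expressed
#' annotated genes (`|A_f` intersect `V_s|`). Scaled variants
#' standardize each function across samples (zero-variance columns
#' scale to 0).
#'
#' @param result an `assignment_result`.
#' @return list of class `activity_profile` with sample x function
#'   matrices `x_diffusion`, `x_annotation`, `x_diffusion_scaled`,
#'   `x_annotation_scaled`, plus `condition`.
#' @export
activity_profiles <- function(result) {
  stopifnot(inherits(result, "assignment_result"))
  samples <- colnames(result$expressed)
  fun_ids <- names(result$collection)
  asg <- result$assignments
  X <- base::table(factor(asg$sample_id, levels = samples),
                   factor(asg$function_id, levels = fun_ids))
  X <- matrix(as.integer(X), length(samples), length(fun_ids),
              dimnames = list(samples, fun_ids))
  Xp <- vapply(fun_ids, function(f) {
    af <- result$collection[[f]]
    colSums(result$expressed[rownames(result$expressed) %in% af, ,
                             drop = FALSE])
  }, numeric(length(samples)))
  dimnames(Xp) <- list(samples, fun_ids)
  zscale <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    out <- sweep(m, 2, mu)
    sweep(out, 2, ifelse(s > 0, s, 1), "/") * rep(ifelse(s > 0, 1, 0),
                                                  each = nrow(m))
  }
  structure(list(x_diffusion = X,
                 x_annotation = Xp,
                 x_diffusion_scaled = zscale(X),
                 x_annotation_scaled = zscale(Xp),
                 condition = result$condition),
            class = "activity_profile")
}

#' Select top/bottom functions as survival-model features
#'
#' Diffusion mode picks the top and bottom `ceiling(k_percent%)`
#' functions ordered by `delta_f`; control mode picks the
#' `2 * ceiling(k_percent%)` functions with the largest absolute
#' control statistic (e.g. log fold change of the median annotated
#' count). Ties break by function ID for determinism.
#'
#' @param deltas a `function_deltas` (or data frame with
#'   `function_id` and `delta_f`).
#' @param k_percent percentage per tail (default 1).
#' @param mode `"diffusion"` or `"control"`.
#' @param control_stat named numeric vector per function, required in
#'   control mode.
#' @return character vector of selected function IDs.
#' @export
select_features <- function(deltas, k_percent = 1,
                            mode = c("diffusion", "control"),
                            control_stat = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(deltas) > 0)
  k <- ceiling(k_percent / 100 * nrow(deltas))
  if (mode == "diffusion") {
    ord <- order(-deltas$delta_f, deltas$function_id)
    top <- deltas$function_id[ord][seq_len(k)]
    ord_b <- order(deltas$delta_f, deltas$function_id)
    bottom <- deltas$function_id[ord_b][seq_len(k)]
    unique(c(top, rev(bottom)))
  } else {
    if (is.null(control_stat)) stop("control mode needs control_stat",
                                    call. = FALSE)
    ids <- deltas$function_id
    stat <- abs(control_stat[ids])
    ids[order(-stat, ids)][seq_len(min(2 * k, length(ids)))]
  }
}
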
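# Per-gene functional gain/loss between two conditions and the
# per-function net-change statistic Delta_f.
#
# For a (gene, function) pair the contingency table counts, among the
# samples where the gene is expressed,
#     n00 = case assigned      n01 = case not assigned
#     n10 = control assigned   n11 = control not assigned
# and the effect size is the cross-product odds ratio
#     theta = (n00 * n11) / (n10 * n01).
# A gain call requires significance and theta >= theta_min; a loss call
# requires significance and theta <= 1 / theta_min.

odds_ratio_2x2 <- function(n00, n01, n10, n11) {
  num <- n00 * n11
  den <- n10 * n01
  if (den == 0 && num == 0) return(NA_real_)
  if (den == 0) return(Inf)
  num / den
}

#' Expression-bias filter between two conditions
#'
#' A gene whose expressed/unexpressed split differs significantly
#' between the two conditions (two-sided Fisher exact test,
#' p-value at or below `p_cutoff`) is excluded from gain/loss calling,
#' since its assignments would track expression rather than network
#' rewiring.
#'
#' @param expressed logical gene x sample matrix.
#' @param condition per-sample condition factor (two levels).
#' @param p_cutoff exclusion threshold (default 0.05).
#' @return data frame `(gene, p, biased)`; `biased = (p <= p_cutoff)`.
#' @export
expression_bias_filter <- function(expressed, condition, p_cutoff = 0.05) {
  condition <- factor(condition)
  stopifnot(nlevels(condition) == 2L, ncol(expressed) == length(condition))
  lv <- levels(condition)
  nA <- sum(condition == lv[1]); nB <- sum(condition == lv[2])
  eA <- rowSums(expressed[, condition == lv[1], drop = FALSE])
  eB <- rowSums(expressed[, condition == lv[2], drop = FALSE])
  key <- paste(eA, eB)
  p_by_key <- vapply(unique(key), function(k) {
    ab <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    stats::fisher.test(matrix(c(ab[1], nA - ab[1], ab[2], nB - ab[2]), 2))$p.value
  }, 0)
  p <- unname(p_by_key[key])
  data.frame(gene = rownames(expressed), p = p, biased = p <= p_cutoff,
             stringsAsFactors = FALSE)
}

#' Gain/loss test for one (gene, function) contingency table
#'
#' @param n00,n01 assigned / not-assigned counts among case samples
#'   where the gene is expressed.
#' @param n10,n11 the same among control samples.
#' @param theta_min minimum odds-ratio effect size (default 10).
#' @param sig significance indicator for the table (nominal p-value or
#'   FDR decision, supplied by the caller).
#' @param effect `"odds"` for the cross-product odds ratio or
#'   `"ratio"` for the ratio of assigned fractions.
#' @return list `(theta, call)` with `call` in `gain`/`loss`/`none`.
#' @export
gain_loss_call <- function(n00, n01, n10, n11, theta_min = 10, sig = TRUE,
                           effect = c("odds", "ratio")) {
  effect <- match.arg(effect)
  theta <- if (effect == "odds") {
    odds_ratio_2x2(n00, n01, n10, n11)
  } else {
    fc <- n00 / (n00 + n01)
    fn <- n10 / (n10 + n11)
    if (fn == 0 && fc == 0) NA_real_ else if (fn == 0) Inf else fc / fn
  }
  call <- "none"
  if (isTRUE(sig) && !is.na(theta)) {
    if (theta >= theta_min) call <- "gain"
    else if (theta <= 1 / theta_min) call <- "loss"
  }
  list(theta = theta, call = call)
}

#' Call per-gene functional gain and loss between two conditions
#'
#' For every function, each candidate gene's assignment counts are
#' tabulated over the samples where the gene is expressed, split by
#' condition, and tested with a two-sided Fisher exact test. Candidate
#' genes are the network genes passing the expression-bias filter;
#' genes never assigned the function in any evaluated sample are
#' implicitly `none` and omitted from the records.
#'
#' @param result an `assignment_result` from [assign_functions()].
#' @param case,control condition labels; `case` plays the tumor role
#'   ("gain" = enriched among case samples). Defaults: the second and
#'   first factor level of `result$condition`.
#' @param theta_min odds-ratio effect-size threshold (default 10).
#' @param sig_mode `"nominal"` (p-value at or below `p_sig`) or
#'   `"fdr"` (Benjamini-Hochberg across the genes tested within each
#'   function, FDR below `fdr_max`).
#' @param p_sig nominal significance cutoff (default 0.05).
#' @param fdr_max FDR cutoff for `sig_mode = "fdr"` (default 0.1).
#' @param bias_p expression-bias exclusion cutoff (default 0.05).
#' @param effect effect-size mode, see [gain_loss_call()].
#' @return data frame of class `gain_loss_records` with one row per
#'   tested (gene, function): counts, `fisher_p`, `adjusted_p`,
#'   `theta`, `call`, `annotated`, `biased`. Attributes: `case`,
#'   `control`, `theta_min`, `sig_mode`, `bias` (the full bias-filter
#'   table), `n_evaluated_genes`.
#' @export
gain_loss <- function(result, case = NULL, control = NULL, theta_min = 10,
                      sig_mode = c("nominal", "fdr"), p_sig = 0.05,
                      fdr_max = 0.1, bias_p = 0.05,
                      effect = c("odds", "ratio")) {
  stopifnot(inherits(result, "assignment_result"))
  sig_mode <- match.arg(sig_mode)
  effect <- match.arg(effect)
  cond <- factor(result$condition)
  lv <- levels(cond)
  if (length(lv) != 2L) stop("gain/loss needs exactly two conditions",
                             call. = FALSE)
  control <- control %||% lv[1]
  case <- case %||% lv[2]
  stopifnot(case %in% lv, control %in% lv, case != control)

  expressed <- result$expressed
  bias <- expression_bias_filter(expressed, cond, bias_p)
  biased <- stats::setNames(bias$biased, bias$gene)
  is_case <- cond == case
  asg <- result$assignments

  # cache Fisher p-values: many genes share a contingency table
  fisher_cache <- new.env(hash = TRUE, parent = emptyenv())
  fisher_p <- function(n00, n01, n10, n11) {
    key <- paste(n00, n01, n10, n11)
    p <- fisher_cache[[key]]
    if (is.null(p)) {
      p <- stats::fisher.test(matrix(c(n00, n10, n01, n11), 2))$p.value
      fisher_cache[[key]] <- p
    }
    p
  }

  records <- lapply(unique(asg$function_id), function(f) {
    af <- result$collection[[f]]
    sub <- asg[asg$function_id == f, ]
    genes <- unique(sub$gene)
    genes <- genes[!biased[genes]]
    if (length(genes) == 0L) return(NULL)
    hit <- matrix(FALSE, length(genes), ncol(expressed),
                  dimnames = list(genes, colnames(expressed)))
    sub <- sub[sub$gene %in% genes, ]
    hit[cbind(match(sub$gene, genes), match(sub$sample_id, colnames(expressed)))] <- TRUE
    expr_g <- expressed[genes, , drop = FALSE]
    n00 <- rowSums(hit[, is_case, drop = FALSE])
    n01 <- rowSums(expr_g[, is_case, drop = FALSE]) - n00
    n10 <- rowSums(hit[, !is_case, drop = FALSE])
    n11 <- rowSums(expr_g[, !is_case, drop = FALSE]) - n10
    p <- mapply(fisher_p, n00, n01, n10, n11)
    data.frame(gene = genes, function_id = f,
               n00 = n00, n01 = n01, n10 = n10, n11 = n11,
               fisher_p = p,
               annotated = genes %in% af,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  records <- do.call(rbind, records[!vapply(records, is.null, TRUE)])
  if (is.null(records)) {
    records <- data.frame(gene = character(), function_id = character(),
                          n00 = integer(), n01 = integer(), n10 = integer(),
                          n11 = integer(), fisher_p = numeric(),
                          annotated = logical(), stringsAsFactors = FALSE)
  }
  records$adjusted_p <- stats::ave(records$fisher_p, records$function_id,
                                   FUN = function(p) stats::p.adjust(p, "BH"))
  sig <- if (sig_mode == "nominal") records$fisher_p <= p_sig
         else records$adjusted_p < fdr_max
  gl <- mapply(function(n00, n01, n10, n11, s) {
    r <- gain_loss_call(n00, n01, n10, n11, theta_min, s, effect)
    c(r$theta, match(r$call, c("none", "gain", "loss")))
  }, records$n00, records$n01, records$n10, records$n11, sig)
  records$theta <- if (nrow(records)) gl[1, ] else numeric()
  records$call <- if (nrow(records)) c("none", "gain", "loss")[gl[2, ]] else character()
  records$biased <- FALSE   # biased genes were excluded above
  structure(records,
            class = c("gain_loss_records", "data.frame"),
            case = case, control = control, theta_min = theta_min,
            sig_mode = sig_mode, effect = effect, bias = bias,
            n_evaluated_genes = sum(!bias$biased))
}

#' Aggregate gain/loss records into per-function net change
#'
#' `Delta_f` is the number of un-annotated genes gaining the function
#' minus the number losing it (annotated genes and expression-biased
#' genes never contribute); positive values mean net gain in the case
#' condition. Also reports `Delta_f / |A_f|` and the log fold change of
#' the mean expressed-annotated-gene count between conditions (the
#' annotation-level activity control).
#'
#' @param records a `gain_loss_records` from [gain_loss()].
#' @param result the matching `assignment_result`.
#' @return data frame of class `function_deltas`: `function_id`,
#'   `n_annotated`, `n_gained`, `n_lost`, `delta_f`,
#'   `normalized_delta`, `annotation_logfc`, plus list-columns
#'   `gained_genes` and `lost_genes`; ordered by decreasing `delta_f`.
#' @export
function_deltas <- function(records, result) {
  stopifnot(inherits(records, "gain_loss_records"),
            inherits(result, "assignment_result"))
  case <- attr(records, "case"); control <- attr(records, "control")
  cond <- factor(result$condition)
  fun_ids <- names(result$collection)
  eligible <- records[!records$annotated & !records$biased, , drop = FALSE]
  rows <- lapply(fun_ids, function(f) {
    af <- result$collection[[f]]
    sub <- eligible[eligible$function_id == f, , drop = FALSE]
    gained <- sort(sub$gene[sub$call == "gain"])
    lost <- sort(sub$gene[sub$call == "loss"])
    data.frame(function_id = f,
               n_annotated = length(af),
               n_gained = length(gained),
               n_lost = length(lost),
               delta_f = length(gained) - length(lost),
               normalized_delta = (length(gained) - length(lost)) / length(af),
               annotation_logfc = annotation_logfc(result, f, case, control),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gained_genes <- lapply(fun_ids, function(f) {
    sub <- eligible[eligible$function_id == f, , drop = FALSE]
    sort(sub$gene[sub$call == "gain"])
  })
  out$lost_genes <- lapply(fun_ids, function(f) {
    sub <- eligible[eligible$function_id == f, , drop = FALSE]
    sort(sub$gene[sub$call == "loss"])
  })
  out <- out[order(-out$delta_f, out$function_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("function_deltas", "data.frame"),
            case = case, control = control,
            theta_min = attr(records, "theta_min"))
}

#' Annotation-level activity log fold change of a function
#'
#' Natural log of the ratio between the mean number of expressed
#' annotated genes in case samples and in control samples. A zero mean
#' on either side yields `Inf`/`-Inf` (flagged sentinel values), and
#' zero on both sides yields `NaN`.
#'
#' @param result an `assignment_result`.
#' @param function_id a function in `result$collection`.
#' @param case,control condition labels.
#' @return scalar log fold change.
#' @export
annotation_logfc <- function(result, function_id, case, control) {
  af <- result$collection[[function_id]]
  if (is.null(af)) stop("unknown function: ", function_id, call. = FALSE)
  counts <- colSums(result$expressed[rownames(result$expressed) %in% af, ,
                                     drop = FALSE])
  cond <- as.character(result$condition)
  log(mean(counts[cond == case]) / mean(counts[cond == control]))
}
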
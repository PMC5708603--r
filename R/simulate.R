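# Synthetic two-condition cohort with planted signal.
#
# The simulator emulates the statistical structure the pipeline
# assumes: cohesive functional modules embedded in a scale-free
# interaction network, and condition-specific expression silencing that
# rewires the network neighborhood of selected un-annotated genes.
# Rewiring is implemented purely through expression: "bridge" genes
# connecting a target gene to a module are silenced in one condition,
# so the target sits next to the module in one condition's network and
# far from it in the other. The static edge list is never edited.

#' Configuration for the synthetic cohort
#'
#' Defaults describe the desk-scale study conditions used throughout
#' the package's validation: 2000 genes, 20 functions of 50-100 genes,
#' 30 samples per condition, 5 planted-gain and 5 planted-loss
#' functions with 15 rewired target genes each.
#'
#' @param n_genes number of genes.
#' @param n_functions number of gene sets (disjoint planted modules).
#' @param size_range inclusive range of module sizes.
#' @param n_gain,n_loss numbers of planted-gain and planted-loss
#'   functions (the rest carry no signal).
#' @param n_samples named vector `c(normal = ..., tumor = ...)`.
#' @param cohesion probability of an intra-module edge.
#' @param n_targets rewired un-annotated genes per planted function.
#' @param n_bridges bridge genes per planted function.
#' @param bridge_module_edges module neighbors per bridge.
#' @param target_bridge_edges bridge neighbors per target.
#' @param pa_m edges per step of the preferential-attachment background
#'   graph.
#' @param expr_meanlog,expr_sdlog log-normal parameters of the "on"
#'   expression state (RPKM scale; defaults give a median around
#'   7 RPKM with roughly 2\% of draws below 1 RPKM, a natural dropout
#'   rate).
#' @param off_meanlog,off_sdlog log-normal parameters of the silenced
#'   state (median 0.1 RPKM).
#' @param mut_effect additive elevation of the coupled event frequency
#'   on planted target genes (missense for gains; nonsense and
#'   deletion CNV for losses).
#' @param rng_seed integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_functions = 20,
                              size_range = c(50, 100),
                              n_gain = 5, n_loss = 5,
                              n_samples = c(normal = 30, tumor = 30),
                              cohesion = 0.15,
                              n_targets = 15, n_bridges = 12,
                              bridge_module_edges = 16,
                              target_bridge_edges = 10,
                              pa_m = 3,
                              expr_meanlog = 2, expr_sdlog = 1,
                              off_meanlog = log(0.1), off_sdlog = 0.5,
                              mut_effect = 0.2, rng_seed = 7) {
  cfg <- as.list(environment())
  stopifnot(n_gain + n_loss <= n_functions,
            target_bridge_edges <= n_bridges,
            bridge_module_edges <= size_range[1],
            all(unlist(cfg[c("n_genes", "n_functions", "n_samples",
                             "n_targets", "n_bridges")]) > 0))
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic two-condition cohort with planted rewiring
#'
#' Generates every input the pipeline consumes — weighted edge list,
#' two-condition expression matrix, gene-set collection, per-gene
#' mutation/CNV frequency table — together with ground-truth tables of
#' the planted (gene, function) gains and losses. Planted-gain bridges
#' are silenced in normal samples (targets approach the module only in
#' tumors); planted-loss bridges are silenced in tumors. Mutation and
#' CNV frequencies are elevated on target genes so that the
#' association-stage hypotheses hold by construction.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_cohort` with elements `edges`
#'   (`edge_list`), `network` (`weighted_network`), `expression`
#'   (`expression_matrix`, conditions `normal`/`tumor`), `collection`
#'   (`gene_set_collection`), `gene_stats` (`gene_stat_table`),
#'   `truth` (list `functions` and `pairs` data frames) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$rng_seed)

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  sizes <- sample(seq(cfg$size_range[1], cfg$size_range[2]),
                  cfg$n_functions, replace = TRUE)
  n_planted <- cfg$n_gain + cfg$n_loss
  needed <- sum(sizes) + n_planted * (cfg$n_targets + cfg$n_bridges)
  if (needed > cfg$n_genes) {
    stop("module + target + bridge genes (", needed,
         ") exceed n_genes (", cfg$n_genes, ")", call. = FALSE)
  }

  pool <- sample(genes)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  fun_ids <- sprintf("F%02d", seq_len(cfg$n_functions))
  direction <- c(rep("gain", cfg$n_gain), rep("loss", cfg$n_loss),
                 rep("none", cfg$n_functions - n_planted))
  modules <- lapply(sizes, take)
  names(modules) <- fun_ids
  planted <- which(direction != "none")
  targets <- lapply(seq_len(cfg$n_functions), function(i) {
    if (direction[i] == "none") character() else take(cfg$n_targets)
  })
  bridges <- lapply(seq_len(cfg$n_functions), function(i) {
    if (direction[i] == "none") character() else take(cfg$n_bridges)
  })

  # scale-free background; PA vertex order is decoupled from gene IDs
  # by the random gene permutation above
  bg <- igraph::as_edgelist(
    igraph::sample_pa(cfg$n_genes, m = cfg$pa_m, directed = FALSE),
    names = FALSE)
  ea <- genes[bg[, 1]]; eb <- genes[bg[, 2]]
  ew <- stats::runif(nrow(bg), 0.3, 1)

  for (i in seq_len(cfg$n_functions)) {
    m <- modules[[i]]
    pairs <- which(upper.tri(diag(length(m))), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < cfg$cohesion
    pairs <- pairs[keep, , drop = FALSE]
    ea <- c(ea, m[pairs[, 1]]); eb <- c(eb, m[pairs[, 2]])
    ew <- c(ew, stats::runif(nrow(pairs), 0.5, 1))
    if (direction[i] != "none") {
      for (b in bridges[[i]]) {
        nb <- sample(m, cfg$bridge_module_edges)
        ea <- c(ea, rep(b, length(nb))); eb <- c(eb, nb)
        ew <- c(ew, stats::runif(length(nb), 0.7, 1))
      }
      for (t in targets[[i]]) {
        nb <- sample(bridges[[i]], cfg$target_bridge_edges)
        ea <- c(ea, rep(t, length(nb))); eb <- c(eb, nb)
        ew <- c(ew, stats::runif(length(nb), 0.7, 1))
      }
    }
  }
  drop_loops <- ea != eb
  edges <- edge_list(ea[drop_loops], eb[drop_loops], ew[drop_loops])
  network <- weighted_network(edges, nodes = genes)

  n_norm <- cfg$n_samples[["normal"]]; n_tum <- cfg$n_samples[["tumor"]]
  samples <- c(sprintf("N%03d", seq_len(n_norm)),
               sprintf("T%03d", seq_len(n_tum)))
  condition <- stats::setNames(rep(c("normal", "tumor"), c(n_norm, n_tum)),
                               samples)
  vals <- matrix(stats::rlnorm(cfg$n_genes * length(samples),
                               cfg$expr_meanlog, cfg$expr_sdlog),
                 cfg$n_genes, length(samples),
                 dimnames = list(genes, samples))
  off_in <- function(gs, cond_label) {
    cols <- which(condition == cond_label)
    vals[gs, cols] <<- stats::rlnorm(length(gs) * length(cols),
                                     cfg$off_meanlog, cfg$off_sdlog)
  }
  for (i in planted) {
    # gain: bridges exist only in tumor networks; loss: only in normal
    off_in(bridges[[i]], if (direction[i] == "gain") "normal" else "tumor")
  }
  expression <- expression_matrix(vals, condition, "rnaseq")

  stats_df <- data.frame(
    gene = genes,
    missense_freq = stats::rbeta(cfg$n_genes, 1, 20),
    nonsense_freq = stats::rbeta(cfg$n_genes, 1, 20),
    cnv_del_freq = stats::rbeta(cfg$n_genes, 1, 20),
    cnv_amp_freq = stats::rbeta(cfg$n_genes, 1, 20),
    stringsAsFactors = FALSE)
  rownames(stats_df) <- genes
  for (i in planted) {
    t <- targets[[i]]
    if (direction[i] == "gain") {
      stats_df[t, "missense_freq"] <-
        pmin(1, stats_df[t, "missense_freq"] + cfg$mut_effect)
    } else {
      stats_df[t, "nonsense_freq"] <-
        pmin(1, stats_df[t, "nonsense_freq"] + cfg$mut_effect)
      stats_df[t, "cnv_del_freq"] <-
        pmin(1, stats_df[t, "cnv_del_freq"] + cfg$mut_effect)
    }
  }
  gene_stats <- gene_stat_table(stats_df)

  truth_pairs <- do.call(rbind, lapply(planted, function(i) {
    data.frame(gene = targets[[i]], function_id = fun_ids[i],
               direction = direction[i], stringsAsFactors = FALSE)
  }))
  truth <- list(
    functions = data.frame(function_id = fun_ids, direction = direction,
                           stringsAsFactors = FALSE),
    pairs = truth_pairs,
    bridges = stats::setNames(bridges, fun_ids))

  structure(list(edges = edges,
                 network = network,
                 expression = expression,
                 collection = gene_set_collection(
                   modules,
                   stats::setNames(paste("planted", direction), fun_ids)),
                 gene_stats = gene_stats,
                 truth = truth,
                 config = cfg),
            class = "simulated_cohort")
}

#' Write all simulated inputs and ground truth to a directory
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(cohort$edges, file.path(dir, "network.tsv"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gmt(cohort$collection, file.path(dir, "functions.gmt"))
  write_gene_stats(cohort$gene_stats, file.path(dir, "gene_stats.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$expression$condition),
               condition = as.character(cohort$expression$condition)),
    file.path(dir, "conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$functions,
                     file.path(dir, "truth_functions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
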
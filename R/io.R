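# Readers/writers for the plain-text formats the pipeline touches:
# weighted edge lists, GMT gene-set collections, expression matrices
# with condition labels, and per-gene event-frequency tables.

#' Read a weighted edge list
#'
#' Reads a whitespace- or tab-delimited file with at least three columns
#' (gene A, gene B, confidence weight). Self-loops are dropped and
#' duplicate undirected pairs are collapsed to the maximum weight, the
#' convention for interaction confidence scores that are maxima over
#' evidence sources.
#'
#' @param path path to the edge-list file.
#' @param verbose log counts of dropped self-loops and collapsed
#'   duplicates.
#' @return a data frame of class `edge_list` with columns `gene_a`,
#'   `gene_b`, `weight`; one row per undirected edge, endpoints in
#'   lexicographic order.
#' @export
read_edge_list <- function(path, verbose = FALSE) {
  if (length(readLines(path, n = 1L)) == 0L) {
    stop("empty edge list: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse edge list '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("empty edge list: ", path, call. = FALSE)
  if (ncol(raw) < 3L) stop("edge list needs >= 3 columns: ", path, call. = FALSE)
  w <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop("unparseable weight '", raw[[3]][bad], "' at line ", bad,
         " of ", path, call. = FALSE)
  }
  edge_list(raw[[1]], raw[[2]], w, verbose = verbose)
}

#' Construct a canonical edge list
#'
#' @param gene_a,gene_b character vectors of endpoint gene symbols.
#' @param weight numeric confidence weights, strictly positive.
#' @param verbose log dropped/collapsed record counts.
#' @return a canonicalized `edge_list` data frame (see
#'   [read_edge_list()]).
#' @export
edge_list <- function(gene_a, gene_b, weight, verbose = FALSE) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  weight <- as.numeric(weight)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    bad <- which(!is.finite(weight) | weight <= 0)[1]
    stop("edge weights must be finite and > 0 (record ", bad, " has ",
         weight[bad], ")", call. = FALSE)
  }
  loop <- gene_a == gene_b
  if (any(loop)) {
    vlog(verbose, "dropping ", sum(loop), " self-loop(s)")
    gene_a <- gene_a[!loop]; gene_b <- gene_b[!loop]; weight <- weight[!loop]
  }
  if (length(gene_a) == 0L) stop("edge list has no non-loop edges", call. = FALSE)
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    vlog(verbose, "collapsing ", sum(duplicated(key)),
         " duplicate undirected pair(s), keeping max weight")
    w <- tapply(weight, key, max)
    key <- names(w)
    parts <- strsplit(key, "\r", fixed = TRUE)
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    weight <- as.numeric(w)
  }
  ord <- order(a, b)
  out <- data.frame(gene_a = a[ord], gene_b = b[ord],
                    weight = weight[ord], stringsAsFactors = FALSE)
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Write an edge list to a tab-separated file
#'
#' @param x an `edge_list`.
#' @param path output path.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "edge_list"))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `ID`,
#' `description`, then member gene symbols. Duplicate genes within a
#' line are removed.
#'
#' @param path path to the GMT file.
#' @return a named list of class `gene_set_collection`: each element a
#'   character vector of member genes, with a `description` attribute
#'   carrying the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1], " has fewer than 3 fields in ",
         path, call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set ID '", ids[duplicated(ids)][1], "' in ",
         path, call. = FALSE)
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(stats::setNames(sets, ids), stats::setNames(desc, ids))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set ID -> member genes).
#' @param description optional named character vector of descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate set IDs", call. = FALSE)
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1], call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, description = description[names(sets)],
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param x a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  desc <- attr(x, "description")
  lines <- vapply(names(x), function(id) {
    paste(c(id, desc[[id]], x[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' TSV with genes in rows and a header row of sample IDs. Every sample
#' must carry a condition label; values must be nonnegative (RPKM for
#' sequencing platforms, intensities for arrays).
#'
#' @param path path to the expression TSV.
#' @param condition_map named character vector mapping sample ID to a
#'   condition label.
#' @param platform `"rnaseq"` or `"array"`.
#' @return an `expression_matrix` (see [expression_matrix()]).
#' @export
read_expression <- function(path, condition_map, platform = c("rnaseq", "array")) {
  platform <- match.arg(platform)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene row '", genes[duplicated(genes)][1], "' in ",
         path, call. = FALSE)
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- genes
  expression_matrix(values, condition_map[colnames(values)], platform)
}

#' Construct an expression matrix with condition labels
#'
#' @param values numeric gene-by-sample matrix, nonnegative, with unique
#'   rownames (gene symbols) and colnames (sample IDs).
#' @param condition character/factor of per-sample condition labels, in
#'   column order or named by sample ID.
#' @param platform `"rnaseq"` or `"array"`.
#' @return a list of class `expression_matrix` with elements `values`,
#'   `condition` (named factor) and `platform`.
#' @export
expression_matrix <- function(values, condition, platform = c("rnaseq", "array")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("expression values must be nonnegative and non-missing", call. = FALSE)
  }
  if (!is.null(names(condition))) condition <- condition[colnames(values)]
  condition <- as.character(condition)
  if (length(condition) != ncol(values) || anyNA(condition)) {
    stop("every sample needs a condition label", call. = FALSE)
  }
  structure(list(values = values,
                 condition = stats::setNames(factor(condition), colnames(values)),
                 platform = platform),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", x$platform, ")\n")
  print(table(x$condition))
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene event-frequency table
#'
#' TSV with a `gene` column and one column per event frequency
#' (e.g. `missense_freq`, `nonsense_freq`, `cnv_del_freq`,
#' `cnv_amp_freq`), each a fraction of samples in `[0, 1]`.
#'
#' @param path path to the table.
#' @return a data frame of class `gene_stat_table`, genes as rownames.
#' @export
read_gene_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("gene-stat table needs a 'gene' column",
                                   call. = FALSE)
  gene_stat_table(df)
}

#' Construct a per-gene event-frequency table
#'
#' @param df data frame with a `gene` column and numeric frequency
#'   columns in `[0, 1]`.
#' @return a `gene_stat_table` with genes as rownames.
#' @export
gene_stat_table <- function(df) {
  stopifnot(is.data.frame(df), "gene" %in% names(df))
  if (anyDuplicated(df$gene)) stop("duplicate genes in stat table", call. = FALSE)
  num <- df[setdiff(names(df), "gene")]
  if (any(vapply(num, function(v) any(v < 0 | v > 1, na.rm = TRUE), TRUE))) {
    stop("event frequencies must lie in [0, 1]", call. = FALSE)
  }
  rownames(df) <- df$gene
  class(df) <- c("gene_stat_table", "data.frame")
  df
}

#' Write a gene-stat table to TSV
#'
#' @param x a `gene_stat_table`.
#' @param path output path.
#' @export
write_gene_stats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
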
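# Null calibration of raw diffusion scores.
#
# A raw score depends on the seed size |A_f intersect V_s| and the
# sample network topology, so significance is judged against random
# seed sets of matching size. Functions are grouped into seed-size bins
# (every member within +/- 10 of the bin's median seed size) and one
# null per bin is estimated from n_boot random diffusions, approximated
# per gene as a normal distribution.

#' Partition functions into seed-size bins
#'
#' Greedy sweep over seed sizes sorted increasingly: a new function
#' joins the current bin as long as every member would stay within
#' `tol` of the running median; otherwise a new bin opens. This keeps
#' the bin count small while guaranteeing the `k +/- tol` constraint.
#'
#' @param seed_sizes named integer vector: per-function seed size
#'   (`|A_f` intersect `V_s|`), names are function IDs.
#' @param tol maximum deviation of a member's seed size from the bin
#'   seed size (default 10).
#' @return data frame with columns `function_id`, `seed_size`,
#'   `bin_id`, `bin_seed_size` (integer-rounded median of members).
#' @export
build_bins <- function(seed_sizes, tol = 10) {
  stopifnot(!is.null(names(seed_sizes)), all(seed_sizes >= 1))
  ord <- order(seed_sizes, names(seed_sizes))
  sizes <- as.integer(seed_sizes[ord])
  ids <- names(seed_sizes)[ord]
  bin_id <- integer(length(sizes))
  bin_center <- integer(0)
  start <- 1L
  current <- 0L
  for (i in seq_along(sizes)) {
    cand <- sizes[start:i]
    med <- as.integer(round(stats::median(cand)))
    if (i == start || all(abs(cand - med) <= tol)) {
      current <- current + (i == start)
      bin_id[start:i] <- current
      bin_center[current] <- med
    } else {
      start <- i
      current <- current + 1L
      bin_id[i] <- current
      bin_center[current] <- sizes[i]
    }
  }
  out <- data.frame(function_id = ids,
                    seed_size = sizes,
                    bin_id = bin_id,
                    bin_seed_size = bin_center[bin_id],
                    stringsAsFactors = FALSE)
  stopifnot(all(abs(out$seed_size - out$bin_seed_size) <= tol))
  out[match(names(seed_sizes), out$function_id), , drop = FALSE]
}

#' Estimate a random-seed null distribution for one seed size
#'
#' Draws `n_boot` uniform random seed sets of the given size (without
#' replacement from the network's nodes), diffuses each, and records
#' the per-gene mean and standard deviation of the resulting scores.
#'
#' @param network a `sample_network` or `weighted_network`, or a
#'   prebuilt [diffusion_operator()] (preferred when estimating several
#'   bins on the same network).
#' @param seed_size number of random seed genes per draw.
#' @param n_boot number of random draws (default 100).
#' @param rng_seed integer RNG seed making the null reproducible.
#' @param alpha restart weight, used when `network` is not already an
#'   operator.
#' @return a list of class `null_bin`: `mean` and `sd` (named per-gene
#'   vectors), `seed_size`, `n_boot`, `rng_seed`.
#' @export
estimate_null <- function(network, seed_size, n_boot = 100, rng_seed = 1,
                          alpha = 0.2) {
  op <- if (inherits(network, "diffusion_operator")) network
        else diffusion_operator(network, alpha)
  n <- length(op$nodes)
  if (seed_size < 1 || seed_size > n) {
    stop("seed_size ", seed_size, " outside [1, ", n, "]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(rng_seed)
  idx_i <- unlist(lapply(seq_len(n_boot), function(b) sample.int(n, seed_size)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  Y <- Matrix::sparseMatrix(i = idx_i,
                            j = rep(seq_len(n_boot), each = seed_size),
                            x = 1, dims = c(n, n_boot))
  F <- op$solve(Y)
  mu <- rowMeans(F)
  sd <- sqrt(pmax(0, (rowSums(F * F) - n_boot * mu^2) / (n_boot - 1)))
  structure(list(mean = stats::setNames(mu, op$nodes),
                 sd = stats::setNames(sd, op$nodes),
                 seed_size = seed_size, n_boot = n_boot,
                 rng_seed = rng_seed),
            class = "null_bin")
}

#' Normal-approximation upper-tail p-value of a raw score
#'
#' @param raw raw diffusion score(s).
#' @param null_mean,null_sd per-gene null mean and standard deviation
#'   (recycled against `raw`).
#' @return upper-tail p-value `P(Z >= (raw - mean) / sd)`; when
#'   `sd == 0` the p-value is 0 if `raw > mean` and 1 otherwise.
#' @export
score_pvalue <- function(raw, null_mean, null_sd) {
  p <- stats::pnorm(raw, mean = null_mean, sd = null_sd, lower.tail = FALSE)
  degenerate <- null_sd == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(raw[degenerate] > null_mean[degenerate], 0, 1)
  }
  p
}

#' Binary assignment of a function from calibrated scores
#'
#' A gene is assigned the function when its raw-score p-value passes
#' the threshold; genes with a zero raw score are never assigned.
#'
#' @param scores named raw score vector (one function, one sample).
#' @param null a `null_bin` for the matching sample network.
#' @param p_threshold assignment threshold (default 0.01, compared
#'   with `<=`).
#' @return named logical vector over the scored genes, with the
#'   p-values attached as attribute `p`.
#' @export
assign_from_null <- function(scores, null, p_threshold = 0.01) {
  stopifnot(inherits(null, "null_bin"),
            length(scores) == length(null$mean))
  p <- score_pvalue(as.numeric(scores), null$mean, null$sd)
  out <- (p <= p_threshold) & (as.numeric(scores) > 0)
  names(out) <- names(null$mean)
  attr(out, "p") <- p
  out
}
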
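# Random-walk-with-restart diffusion over a sample network.
#
# The propagation fixed point is
#   F = (1 - alpha) * S %*% F + alpha * Y,    S = D^{-1/2} W D^{-1/2}
# with restart weight alpha in (0, 1), equivalently
#   F = alpha * (I - (1 - alpha) * S)^{-1} %*% Y.
# The system matrix is symmetric positive definite (the eigenvalues of
# S lie in [-1, 1]), so it is solved by conjugate gradients; a sparse
# Cholesky path is used when many right-hand sides share one network.

#' Symmetrically normalized adjacency operator
#'
#' Computes `S = D^{-1/2} W D^{-1/2}` for a network. Rows and columns of
#' zero-degree (isolated) nodes are left at zero, so S stays symmetric
#' with spectral radius at most 1.
#'
#' @param network a `sample_network` or `weighted_network`.
#' @return a symmetric sparse matrix with the network's node names.
#' @export
symmetric_normalize <- function(network) {
  d <- network$degree
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- Matrix::Diagonal(x = inv_sqrt) %*% network$adjacency %*%
    Matrix::Diagonal(x = inv_sqrt)
  dimnames(S) <- dimnames(network$adjacency)
  S
}

#' Seed vector for a function on a sample network
#'
#' Binary indicator over the network's nodes, 1 at annotated genes that
#' are present in the network (`A_f` intersected with `V_s`). Annotated
#' genes that are not expressed in the sample are silently excluded.
#'
#' @param network a `sample_network` or `weighted_network`.
#' @param annotated character vector of annotated gene symbols `A_f`.
#' @return a named 0/1 numeric vector over `network$nodes` with
#'   attribute `seed_size`.
#' @export
seed_vector <- function(network, annotated) {
  y <- as.numeric(network$nodes %in% annotated)
  names(y) <- network$nodes
  attr(y, "seed_size") <- sum(y)
  y
}

# Conjugate gradients for M x = b with M = I - (1 - alpha) S, SPD.
cg_solve <- function(S, b, alpha, rtol = 1e-10, maxit = NULL) {
  n <- length(b)
  maxit <- maxit %||% max(100L, 10L * n)
  matvec <- function(x) x - (1 - alpha) * as.numeric(S %*% x)
  x <- numeric(n)
  r <- b                      # b - M %*% 0
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Mp <- matvec(p)
    a <- rs / sum(p * Mp)
    x <- x + a * p
    r <- r - a * Mp
    rs_new <- sum(r * r)
    if (sqrt(rs_new) <= rtol * bnorm) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  stop("conjugate gradient did not converge in ", maxit,
       " iterations (relative residual ", sqrt(rs) / bnorm, ")",
       call. = FALSE)
}

#' Precompute a per-network diffusion operator
#'
#' Factorizes `I - (1 - alpha) S` once (sparse Cholesky) so that many
#' seed vectors can be propagated over the same network cheaply, e.g.
#' all functions plus all null bootstrap draws of one sample.
#'
#' @param network a `sample_network` or `weighted_network`.
#' @param alpha restart weight in (0, 1).
#' @return a `diffusion_operator` with a `$solve(B)` method mapping a
#'   seed matrix (nodes x k) to diffusion scores.
#' @export
diffusion_operator <- function(network, alpha = 0.2) {
  stopifnot(alpha > 0, alpha < 1)
  S <- symmetric_normalize(network)
  n <- nrow(S)
  M <- Matrix::forceSymmetric(Matrix::Diagonal(n) - (1 - alpha) * S)
  ch <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
  structure(list(
    nodes = network$nodes,
    alpha = alpha,
    S = S,
    solve = function(B) {
      out <- alpha * as.matrix(Matrix::solve(ch, B, system = "A"))
      out[out < 0] <- 0   # clip solver round-off; true solution is >= 0
      rownames(out) <- network$nodes
      out
    }
  ), class = "diffusion_operator")
}

#' Propagate a seed vector over a network
#'
#' Solves the restart-diffusion linear system for one seed vector and
#' returns the raw involvement score of every node. The default solver
#' is conjugate gradients on the symmetric positive-definite system;
#' convergence is verified against the fixed-point residual.
#'
#' @param network a `sample_network` or `weighted_network`.
#' @param seeds either a character vector of seed gene symbols or a
#'   numeric seed vector over `network$nodes` (see [seed_vector()]).
#' @param alpha restart weight in (0, 1); 0.2 by default, following
#'   the random-walk-with-restart literature.
#' @param method `"cg"` (conjugate gradients) or `"direct"` (sparse
#'   Cholesky); both satisfy the same residual contract.
#' @param rtol relative CG tolerance.
#' @return named nonnegative score vector over `network$nodes` with
#'   attributes `alpha` and `residual` (max-norm fixed-point residual).
#' @export
diffuse <- function(network, seeds, alpha = 0.2,
                    method = c("cg", "direct"), rtol = 1e-10) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  y <- if (is.character(seeds)) seed_vector(network, seeds) else as.numeric(seeds)
  if (length(y) != length(network$nodes)) {
    stop("seed vector length does not match network size", call. = FALSE)
  }
  S <- symmetric_normalize(network)
  if (method == "cg") {
    f <- alpha * cg_solve(S, y, alpha, rtol = rtol)
  } else {
    op <- diffusion_operator(network, alpha)
    f <- as.numeric(op$solve(matrix(y, ncol = 1)))
  }
  f[f < 0] <- 0
  resid <- max(abs(f - (1 - alpha) * as.numeric(S %*% f) - alpha * y))
  names(f) <- network$nodes
  attr(f, "alpha") <- alpha
  attr(f, "residual") <- resid
  f
}
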
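# Small in-code fixtures shared across tests.

# Named graphs as edge lists.
fixture_path3 <- function() {
  weighted_network(edge_list(c("A", "B"), c("B", "C"), c(1, 1)))
}

fixture_star <- function(k = 3, w = 1) {
  leaves <- paste0("L", seq_len(k))
  weighted_network(edge_list(rep("hub", k), leaves, rep(w, k)))
}

fixture_cycle <- function(n = 12, w = 1) {
  v <- sprintf("c%02d", seq_len(n))
  weighted_network(edge_list(v, v[c(2:n, 1)], rep(w, n)))
}

# Circulant lattice C_n(1..k): vertex-transitive with 2k neighbors per
# node, so null score distributions are identical across genes and each
# score sums many comparable contributions.
fixture_circulant <- function(n = 60, k = 3) {
  v <- sprintf("c%03d", seq_len(n))
  ea <- c(); eb <- c()
  for (s in seq_len(k)) {
    ea <- c(ea, v)
    eb <- c(eb, v[(seq_len(n) + s - 1L) %% n + 1L])
  }
  weighted_network(edge_list(ea, eb, rep(1, length(ea))))
}

# Erdos-Renyi-ish random weighted network, deterministic given seed.
fixture_random <- function(n = 25, p = 0.15, seed = 42) {
  set.seed(seed)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  v <- sprintf("v%02d", seq_len(n))
  weighted_network(edge_list(v[pairs[, 1]], v[pairs[, 2]],
                             runif(nrow(pairs), 0.2, 1)),
                   nodes = v)
}

# Expression matrix where every listed gene is "on" everywhere.
fixture_expression <- function(genes, samples, condition,
                               value = 10, platform = "rnaseq") {
  m <- matrix(value, length(genes), length(samples),
              dimnames = list(genes, samples))
  expression_matrix(m, condition, platform)
}

# Small cohort shared by the slower end-to-end unit tests: planted
# modules kept at roughly the default module-to-graph ratio so the
# rewiring signal survives the null calibration at reduced scale.
fixture_mini_cohort <- function(seed = 3) {
  simulate_cohort(simulation_config(
    n_genes = 800, n_functions = 4, size_range = c(30, 40),
    n_gain = 1, n_loss = 1, n_samples = c(normal = 15, tumor = 15),
    n_targets = 8, n_bridges = 10, bridge_module_edges = 20,
    target_bridge_edges = 10, rng_seed = seed))
}
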
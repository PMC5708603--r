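test_that("seed-size binning satisfies the +/-10 window and matches the minimal-partition oracle", {
  b1 <- build_bins(c(f1 = 50, f2 = 55, f3 = 60))
  expect_equal(length(unique(b1$bin_id)), 1L)
  expect_equal(unique(b1$bin_seed_size), 55L)

  b2 <- build_bins(c(f1 = 50, f2 = 100))
  expect_equal(length(unique(b2$bin_id)), 2L)

  sizes <- setNames(seq(50, 90, by = 5), paste0("f", 1:9))
  b3 <- build_bins(sizes)
  expect_true(all(abs(b3$seed_size - b3$bin_seed_size) <= 10))
  expect_equal(length(unique(b3$bin_id)), oracle_min_bins(sizes, 10))

  # every function in exactly one bin, on random instances
  set.seed(8)
  for (rep in 1:5) {
    sz <- setNames(sample(30:400, 40, replace = TRUE), paste0("g", 1:40))
    bb <- build_bins(sz)
    expect_equal(sort(bb$function_id), sort(names(sz)))
    expect_true(all(abs(bb$seed_size - bb$bin_seed_size) <= 10))
  }
})

test_that("degenerate null with seed size |V| has zero spread", {
  net <- fixture_cycle(8)
  nb <- estimate_null(net, seed_size = 8, n_boot = 20, rng_seed = 1)
  expect_equal(unname(nb$sd), rep(0, 8))
  expect_error(estimate_null(net, seed_size = 9), "outside")
})

test_that("null means are symmetric on a vertex-transitive fixture", {
  net <- fixture_cycle(20)
  nb <- estimate_null(net, seed_size = 5, n_boot = 400, rng_seed = 3)
  # all genes share the same null mean within Monte-Carlo error
  expect_lt(diff(range(nb$mean)) / mean(nb$mean), 0.25)
})

test_that("sampled size-1 null means agree with exhaustive enumeration", {
  net <- fixture_random(20, 0.2, seed = 13)
  op <- diffusion_operator(net, 0.2)
  # enumerate every single-gene seed set exactly
  F_all <- op$solve(diag(20))
  exact_mean <- rowMeans(F_all)
  nb <- estimate_null(net, seed_size = 1, n_boot = 400, rng_seed = 5)
  # Monte-Carlo error bound: a few standard errors of the draw
  se <- apply(F_all, 1, sd) / sqrt(400)
  expect_true(all(abs(nb$mean - exact_mean) < 5 * se + 1e-12))
})

test_that("null estimation is deterministic given its seed", {
  net <- fixture_random(15, 0.25, seed = 4)
  a <- estimate_null(net, 4, n_boot = 50, rng_seed = 99)
  b <- estimate_null(net, 4, n_boot = 50, rng_seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- estimate_null(net, 4, n_boot = 50, rng_seed = 100)
  expect_false(identical(a$mean, c$mean))
})

test_that("score p-values follow the normal tail with degenerate-sd conventions", {
  expect_equal(score_pvalue(1, 1, 0.5), 0.5)
  # 2.3263 is the rounded 1% standard-normal quantile
  expect_equal(score_pvalue(1 + 2.3263 * 0.5, 1, 0.5), 0.01, tolerance = 1e-3)
  expect_equal(score_pvalue(c(2, 1, 0.5), c(1, 1, 1), c(0, 0, 0)), c(0, 1, 1))
})

test_that("assignment respects the zero-score rule and threshold monotonicity", {
  net <- fixture_random(20, 0.2, seed = 21)
  nb <- estimate_null(net, 3, n_boot = 100, rng_seed = 7)
  zero <- setNames(rep(0, 20), net$nodes)
  expect_false(any(assign_from_null(zero, nb)))

  f <- diffuse(net, net$nodes[1:3])
  a_strict <- assign_from_null(f, nb, p_threshold = 0.001)
  a_loose <- assign_from_null(f, nb, p_threshold = 0.01)
  expect_true(all(which(a_strict) %in% which(a_loose)))
})

test_that("seed genes of a planted clique are assigned against the random null", {
  # 6-clique weakly attached to a 30-node background
  v <- c(paste0("k", 1:6), paste0("b", 1:30))
  pairs <- t(combn(6, 2))
  ea <- c(v[pairs[, 1]], "k1", paste0("b", 1:29))
  eb <- c(v[pairs[, 2]], "b1", paste0("b", 2:30))
  net <- weighted_network(edge_list(ea, eb, c(rep(1, nrow(pairs)), rep(0.3, 30))))
  clique <- paste0("k", 1:6)
  f <- diffuse(net, clique)
  nb <- estimate_null(net, 6, n_boot = 200, rng_seed = 11)
  hits <- assign_from_null(f, nb, 0.01)
  expect_true(all(hits[clique]))
  # permutation oracle: empirical p of each clique gene is extreme
  op <- diffusion_operator(net, 0.2)
  set.seed(2)
  emp <- replicate(500, {
    y <- as.numeric(seq_along(net$nodes) %in% sample(length(net$nodes), 6))
    op$solve(matrix(y, ncol = 1))[match(clique, net$nodes), 1]
  })
  emp_p <- rowMeans(emp >= f[clique])
  expect_true(all(emp_p <= 0.01))
})

test_that("assignment counts at thresholds 0.01 and 0.001 are strongly rank-correlated", {
  co <- fixture_mini_cohort(seed = 5)
  res01 <- assign_functions(co$network, co$expression, co$collection,
                            global_seed = 42, p_threshold = 0.01)
  res001 <- assign_functions(co$network, co$expression, co$collection,
                             global_seed = 42, p_threshold = 0.001)
  x1 <- activity_profiles(res01)$x_diffusion
  x2 <- activity_profiles(res001)$x_diffusion
  rho <- sapply(colnames(x1), function(f) {
    if (sd(x1[, f]) == 0 || sd(x2[, f]) == 0) return(NA_real_)
    cor(x1[, f], x2[, f], method = "spearman")
  })
  expect_gt(median(rho, na.rm = TRUE), 0.5)
  # strict threshold assigns a subset per (gene, function, sample)
  key <- function(df) paste(df$gene, df$function_id, df$sample_id)
  expect_true(all(key(res001$assignments) %in% key(res01$assignments)))
})
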
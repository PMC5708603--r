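test_that("expression-bias filter keeps balanced genes and drops extreme imbalance", {
  genes <- c("balanced", "cancer_only", "skewed")
  expressed <- rbind(
    balanced = rep(TRUE, 30),
    cancer_only = rep(c(FALSE, TRUE), each = 15),
    skewed = c(rep(TRUE, 15), rep(c(TRUE, FALSE), c(3, 12))))
  colnames(expressed) <- paste0("s", 1:30)
  cond <- rep(c("normal", "tumor"), each = 15)
  bias <- expression_bias_filter(expressed, cond)
  expect_equal(bias$p[bias$gene == "balanced"], 1)
  expect_false(bias$biased[bias$gene == "balanced"])
  expect_true(bias$biased[bias$gene == "cancer_only"])
})

test_that("bias decision on counts (55,55;5,105) matches the hypergeometric oracle", {
  expressed <- matrix(c(rep(TRUE, 55), rep(FALSE, 55),
                        rep(TRUE, 5), rep(FALSE, 105)), nrow = 1)
  rownames(expressed) <- "g"
  colnames(expressed) <- paste0("s", 1:220)
  cond <- rep(c("A", "B"), c(110, 110))
  bias <- expression_bias_filter(expressed, cond)
  p_oracle <- oracle_fisher_2x2(55, 55, 5, 105)
  expect_equal(bias$p, p_oracle, tolerance = 1e-6)
  expect_true(bias$biased)
})

test_that("gain/loss calls follow the odds-ratio and significance rules", {
  # identical assignment fractions -> theta 1, no call
  r <- gain_loss_call(10, 40, 10, 40, theta_min = 10, sig = FALSE)
  expect_equal(r$theta, 1)
  expect_equal(r$call, "none")

  # strong enrichment: theta = 99, gain at theta_min = 10
  p <- oracle_fisher_2x2(50, 50, 1, 99)
  expect_lt(p, 1e-10)
  r2 <- gain_loss_call(50, 50, 1, 99, theta_min = 10, sig = p <= 0.05)
  expect_equal(r2$theta, 99)
  expect_equal(r2$call, "gain")

  # zero-cell conventions
  expect_equal(gain_loss_call(5, 45, 0, 50, sig = TRUE, theta_min = 2)$theta, Inf)
  expect_equal(gain_loss_call(5, 45, 0, 50, sig = TRUE, theta_min = 2)$call, "gain")
  expect_equal(gain_loss_call(0, 50, 5, 45, sig = TRUE, theta_min = 2)$theta, 0)
  expect_equal(gain_loss_call(0, 50, 5, 45, sig = TRUE, theta_min = 2)$call, "loss")
  expect_true(is.na(gain_loss_call(0, 50, 0, 50, sig = TRUE)$theta))
  expect_equal(gain_loss_call(0, 50, 0, 50, sig = TRUE)$call, "none")

  # ratio-of-fractions alternative mode
  r3 <- gain_loss_call(30, 30, 10, 50, theta_min = 2, sig = TRUE,
                       effect = "ratio")
  expect_equal(r3$theta, (30 / 60) / (10 / 60))
})

test_that("gain and loss are mutually exclusive and theta stringency is monotone", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 4, replace = TRUE)
    r10 <- gain_loss_call(n[1], n[2], n[3], n[4], theta_min = 10, sig = TRUE)
    r2 <- gain_loss_call(n[1], n[2], n[3], n[4], theta_min = 2, sig = TRUE)
    expect_false(r10$call == "gain" && r10$call == "loss")
    # raising theta never turns none into a call
    if (r10$call != "none") expect_equal(r2$call, r10$call)
  }
})

test_that("delta aggregation excludes annotated genes and uses the sign convention", {
  co <- fixture_mini_cohort(seed = 7)
  res <- assign_functions(co$network, co$expression, co$collection,
                          global_seed = 21)
  rec <- gain_loss(res, case = "tumor", control = "normal", theta_min = 2)
  del <- function_deltas(rec, res)
  for (i in seq_len(nrow(del))) {
    f <- del$function_id[i]
    af <- co$collection[[f]]
    expect_length(intersect(del$gained_genes[[i]], af), 0)
    expect_length(intersect(del$lost_genes[[i]], af), 0)
    expect_length(intersect(del$gained_genes[[i]], del$lost_genes[[i]]), 0)
    expect_equal(del$delta_f[i], del$n_gained[i] - del$n_lost[i])
    expect_equal(del$normalized_delta[i], del$delta_f[i] / length(af))
  }
  # planted directions at mini scale
  truth <- co$truth$functions
  gain_f <- truth$function_id[truth$direction == "gain"]
  loss_f <- truth$function_id[truth$direction == "loss"]
  expect_gt(del$delta_f[del$function_id == gain_f], 0)
  expect_lt(del$delta_f[del$function_id == loss_f], 0)
})

test_that("swapping condition labels negates deltas and swaps gains with losses", {
  co <- fixture_mini_cohort(seed = 11)
  res <- assign_functions(co$network, co$expression, co$collection,
                          global_seed = 33)
  fwd <- gain_loss(res, case = "tumor", control = "normal", theta_min = 2)
  rev <- gain_loss(res, case = "normal", control = "tumor", theta_min = 2)
  key <- paste(fwd$gene, fwd$function_id)
  key_rev <- paste(rev$gene, rev$function_id)
  expect_setequal(key, key_rev)
  m <- match(key, key_rev)
  swap <- c(gain = "loss", loss = "gain", none = "none")
  expect_equal(unname(swap[fwd$call]), rev$call[m])
  d_fwd <- function_deltas(fwd, res)
  d_rev <- function_deltas(rev, res)
  mm <- match(d_fwd$function_id, d_rev$function_id)
  expect_equal(d_fwd$delta_f, -d_rev$delta_f[mm])
})

test_that("annotation log fold change matches a direct tally", {
  genes <- paste0("g", 1:4)
  net <- weighted_network(edge_list(genes[c(1, 2, 3)], genes[c(2, 3, 4)],
                                    rep(1, 3)))
  vals <- matrix(c(5, 5, 5, 5,    # s1 normal: all 4 expressed
                   5, 5, 0, 0,    # s2 normal: 2 expressed
                   5, 5, 5, 0,    # s3 tumor: 3 expressed
                   5, 5, 5, 5),   # s4 tumor: 4 expressed
                 4, 4, dimnames = list(genes, paste0("s", 1:4)))
  em <- expression_matrix(vals, c("normal", "normal", "tumor", "tumor"))
  coll <- gene_set_collection(list(fA = genes))
  res <- assign_functions(net, em, coll, global_seed = 1)
  # mean counts: tumor (3+4)/2 = 3.5, normal (4+2)/2 = 3
  expect_equal(annotation_logfc(res, "fA", "tumor", "normal"), log(3.5 / 3))

  # identical expression in both conditions -> 0
  em0 <- expression_matrix(matrix(5, 4, 4, dimnames = dimnames(vals)),
                           c("normal", "normal", "tumor", "tumor"))
  res0 <- assign_functions(net, em0, coll, global_seed = 1)
  expect_equal(annotation_logfc(res0, "fA", "tumor", "normal"), 0)

  # annotated genes expressed in one condition only -> +Inf sentinel
  res1 <- res
  res1$expressed[, c("s1", "s2")] <- FALSE
  expect_equal(annotation_logfc(res1, "fA", "tumor", "normal"), Inf)
})
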
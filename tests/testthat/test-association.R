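test_that("elevated-statistic test flags extreme separation and matches the permutation oracle", {
  set_v <- seq(0.5, 0.9, length.out = 10)
  bg_v <- seq(0.01, 0.3, length.out = 100)
  r <- elevated_stat_test(set_v, bg_v)
  expect_equal(r$flag, 1L)

  expect_equal(elevated_stat_test(numeric(0), bg_v),
               list(p = 1, flag = 0L, n_set = 0L, n_background = 100L))

  # tie-heavy exact p against exhaustive enumeration, n <= 8
  set.seed(19)
  for (i in 1:20) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    vals <- sample(c(0, 0.1, 0.1, 0.2, 0.3), nx + ny, replace = TRUE)
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(elevated_stat_test(x, y, method = "exact")$p,
                 oracle_wilcoxon_greater(x, y), tolerance = 1e-12)
  }
})

test_that("a set sampled from the background triggers at roughly the nominal rate", {
  set.seed(77)
  bg <- rbeta(300, 1, 10)
  flags <- replicate(400, {
    idx <- sample(300, 12)
    elevated_stat_test(bg[idx], bg[-idx], method = "normal")$flag
  })
  expect_gt(mean(flags), 0.01)
  expect_lt(mean(flags), 0.12)
})

test_that("class enrichment returns the cross-product odds ratio and an exact Fisher p", {
  sym <- class_enrichment(matrix(c(4, 4, 4, 4), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)

  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    ce <- class_enrichment(tab)
    expected_or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    if (is.finite(expected_or) || tab[1, 1] * tab[2, 2] > 0) {
      expect_equal(ce$odds_ratio, expected_or)
    }
    expect_equal(ce$p, oracle_fisher_2x2(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 tolerance = 1e-7)
  }
})

test_that("rank correlation handles monotone, reversed and tied inputs", {
  x <- 1:8
  expect_equal(delta_stat_correlation(x, x^3), 1)
  expect_equal(delta_stat_correlation(x, -2 * x), -1)
  set.seed(3)
  a <- c(1, 2, 2, 3, 5, 5)
  b <- c(0.1, 0.4, 0.2, 0.2, 0.9, 0.7)
  expect_equal(delta_stat_correlation(a, b), oracle_spearman(a, b))
  expect_error(delta_stat_correlation(1:2, 1:2), ">= 3")
})

test_that("driver AUC matches brute-force pair counting and behaves at the extremes", {
  scores <- c(a = 0.9, b = 0.8, c = 0.5, d = 0.2, e = 0.1)
  top <- driver_auc(scores, c("a", "b"), n_perm = 200, rng_seed = 1)
  expect_equal(top$auc, 1.0)

  set.seed(31)
  for (i in 1:20) {
    s <- setNames(sample(c(runif(4), rep(0.5, 3))), paste0("g", 1:7))
    pos <- names(s)[sample(7, 2)]
    expect_equal(driver_auc(s, pos, n_perm = 10, rng_seed = 1)$auc,
                 oracle_auc_pairs(s, names(s) %in% pos))
  }

  # invariance under strictly monotone transforms
  s <- setNames(runif(20), paste0("g", 1:20))
  pos <- paste0("g", 1:5)
  expect_equal(driver_auc(s, pos, n_perm = 50, rng_seed = 9)$auc,
               driver_auc(exp(3 * s), pos, n_perm = 50, rng_seed = 9)$auc)

  # random labels give AUC near 0.5 on average
  set.seed(55)
  aucs <- replicate(200, driver_auc(s, sample(names(s), 5), n_perm = 2,
                                    rng_seed = 1)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  expect_error(driver_auc(s, names(s)), "strict subset")
})

test_that("activity profiles tally the tensor and guard zero variance", {
  co <- fixture_mini_cohort(seed = 13)
  res <- assign_functions(co$network, co$expression, co$collection,
                          global_seed = 8,
                          samples = colnames(co$expression$values)[1:3])
  ap <- activity_profiles(res)
  # direct tally oracle on the 3-sample tensor
  for (s in rownames(ap$x_diffusion)) {
    for (f in colnames(ap$x_diffusion)) {
      expect_equal(ap$x_diffusion[s, f],
                   sum(res$assignments$sample_id == s &
                         res$assignments$function_id == f))
      af <- co$collection[[f]]
      expect_equal(ap$x_annotation[s, f], sum(res$expressed[, s] &
                                                rownames(res$expressed) %in% af))
      expect_lte(ap$x_annotation[s, f], length(af))
    }
  }

  # no assignments -> all-zero diffusion profile
  res0 <- res
  res0$assignments <- res$assignments[0, ]
  ap0 <- activity_profiles(res0)
  expect_true(all(ap0$x_diffusion == 0))

  # constant annotation column scales to zero
  resC <- res
  resC$expressed[] <- TRUE
  apC <- activity_profiles(resC)
  expect_true(all(apC$x_annotation_scaled == 0))
})

test_that("feature selection takes top and bottom tails with deterministic ties", {
  del <- data.frame(function_id = sprintf("F%03d", 1:100),
                    delta_f = c(50, -50, rep(0, 98)))
  picked <- select_features(del, k_percent = 1)
  expect_equal(picked, c("F001", "F002"))

  # all equal: both tails resolve by ID order and overlap collapses
  del2 <- data.frame(function_id = sprintf("F%03d", 5:1), delta_f = rep(1, 5))
  expect_equal(select_features(del2, k_percent = 20), "F001")

  # 1184 functions at 1% per tail -> 24 features
  del3 <- data.frame(function_id = sprintf("F%04d", 1:1184),
                     delta_f = seq(-600, 583))
  expect_length(select_features(del3, k_percent = 1), 24)

  ctl <- setNames(abs(del$delta_f) + seq(0.001, 0.1, length.out = 100), del$function_id)
  picked_ctl <- select_features(del, k_percent = 1, mode = "control",
                                control_stat = ctl)
  expect_length(picked_ctl, 2)
  expect_error(select_features(del, mode = "control"), "control_stat")
})

test_that("gene tendencies count calls over evaluated functions", {
  rec <- structure(
    data.frame(gene = c("a", "a", "b", "c", "a"),
               function_id = c("f1", "f2", "f1", "f2", "f3"),
               call = c("gain", "gain", "loss", "none", "loss"),
               annotated = c(FALSE, FALSE, FALSE, FALSE, TRUE),
               biased = FALSE, stringsAsFactors = FALSE),
    class = c("gain_loss_records", "data.frame"))
  td <- gene_tendency(rec, n_functions = 3)
  expect_equal(td$gain_tendency[td$gene == "a"], 2 / 3)
  expect_equal(td$loss_tendency[td$gene == "a"], 0)   # annotated row excluded
  expect_equal(td$loss_tendency[td$gene == "b"], 1 / 3)
  expect_true(all(td$gain_tendency >= 0 & td$gain_tendency <= 1))
})
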
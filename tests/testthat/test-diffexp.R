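test_that("rank-sum test matches exact enumeration on the canonical example", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3)), 0.1)  # symmetry
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5)), 1)
})

test_that("rank-sum test equals the enumeration oracle for all small cases", {
  withr::local_seed(7)
  for (rep in 1:30) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    # integer draws force ties regularly
    a <- sample(1:5, na, replace = TRUE)
    b <- sample(1:5, nb, replace = TRUE)
    if (max(c(a, b)) == min(c(a, b))) next
    expect_equal(rank_sum_test(a, b), enum_rank_sum(a, b), tolerance = 1e-9)
  }
})

test_that("large-sample path agrees with the tie-corrected normal test", {
  withr::local_seed(8)
  a <- rnorm(40); b <- rnorm(55) + 0.4
  ours <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
  # with heavy ties, against the tie-corrected normal approximation
  a <- sample(1:4, 60, replace = TRUE); b <- sample(1:4, 45, replace = TRUE)
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)$p.value)
  expect_equal(rank_sum_test(a, b), ref, tolerance = 1e-9)
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_equal(adjust_fdr(rep(1, 4)), rep(1, 4))
  withr::local_seed(9)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted p
  perm <- sample(50)
  expect_equal(adjust_fdr(p[perm]), q[perm])     # order invariant
  expect_error(adjust_fdr(c(0.5, 0)), "0, 1")
})

test_that("condition contrast is antisymmetric under label swap", {
  sim <- simulate_retina(synth_config(cells_per_condition_stage = 40L,
                                      n_genes = 250L, seed = 16L))
  expr <- normalize_fraction_umi(sim$table)
  cfg <- pipeline_config(rng_seed = 16L)
  cc1 <- suppressWarnings(condition_contrast(expr, sim$table$cell_type,
                                             sim$table$condition, cfg))
  swapped <- ifelse(sim$table$condition == "native", "organoid", "native")
  cc2 <- suppressWarnings(condition_contrast(expr, sim$table$cell_type,
                                             swapped, cfg))
  key1 <- paste(cc1$gene, cc1$cell_type, cc1$contrast)
  flip <- c(native_gt_organoid = "organoid_gt_native",
            organoid_gt_native = "native_gt_organoid")
  key2 <- paste(cc2$gene, cc2$cell_type, flip[cc2$contrast])
  expect_setequal(key1, key2)
  m <- match(key1, key2)
  expect_equal(cc1$log_fold_change, -cc2$log_fold_change[m])
  expect_equal(cc1$p_value, cc2$p_value[m], tolerance = 1e-12)
})

test_that("shuffling condition labels controls the q-level false positives", {
  sim <- simulate_retina(synth_config(cells_per_condition_stage = 40L,
                                      n_genes = 250L, perturb_log_fold = 0,
                                      seed = 17L))
  expr <- normalize_fraction_umi(sim$table)
  cfg <- pipeline_config(rng_seed = 17L)
  withr::local_seed(17)
  shuffled <- sample(sim$table$condition)
  cc <- suppressWarnings(condition_contrast(expr, sim$table$cell_type,
                                            shuffled, cfg))
  # families = (type, direction); expected passing fraction bounded by q
  n_family_tests <- 250L
  expect_lte(nrow(cc), ceiling(0.01 * 2 * 13 * n_family_tests) + 5L)
})

test_that("TF specificity folds are plain mean ratios", {
  # gene tf1: type means 0.3 / 0.1 -> fold 3, flagged
  # gene tf2: type means 0.15 / 0.12 -> fold 1.25, not flagged
  vals <- rbind(c(0.3, 0.15, 0.55), c(0.3, 0.15, 0.55),
                c(0.1, 0.12, 0.78), c(0.1, 0.12, 0.78))
  expr <- make_expr(vals, gene_ids = c("tf1", "tf2", "other"))
  types <- c("RGC", "RGC", "AC", "AC")
  specifying <- data.frame(gene = c("tf1", "tf2"),
                           cell_type = "RGC", contrast = "type_vs_rest",
                           log_fold_change = 1, p_value = 1e-5,
                           q_value = 1e-4)
  tfa <- tf_specificity(expr, types, specifying,
                        gene_list("tf", c("tf1", "tf2")))
  expect_equal(tfa$specificity_fold[tfa$gene == "tf1"], 3, tolerance = 1e-6)
  expect_true(tfa$flagged[tfa$gene == "tf1"])
  expect_equal(tfa$specificity_fold[tfa$gene == "tf2"], 1.25,
               tolerance = 1e-6)
  expect_false(tfa$flagged[tfa$gene == "tf2"])
})

test_that("planted high-specificity TFs are flagged on synthetic data", {
  sim <- default_sim_cached()
  expr <- normalize_fraction_umi(sim$table)
  cfg <- pipeline_config(rng_seed = 42L)
  spec <- cell_type_specifying(expr, sim$table$cell_type, cfg)
  tfa <- tf_specificity(expr, sim$table$cell_type, spec,
                        gene_list("tf", sim$truth$tf_genes),
                        fold = cfg$tf_fold)
  # markers are boosted exp(1.5) ~ 4.5x in one type only -> nearly all flagged
  expect_gte(mean(tfa$flagged), 0.9)
})

test_that("bootstrap CI collapses on constants and is seed-stable", {
  ci <- bootstrap_mean_ci(rep(3.5, 20), seed = 5L)
  expect_equal(unname(ci), c(3.5, 3.5, 3.5))
  x <- rnorm(50)
  ci1 <- bootstrap_mean_ci(x, seed = 6L)
  ci2 <- bootstrap_mean_ci(x, seed = 6L)
  expect_identical(ci1, ci2)
  expect_lte(ci1["lo"], ci1["mean"])
  expect_gte(ci1["hi"], ci1["mean"])
  expect_error(bootstrap_mean_ci(numeric(0)), "value")
})
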
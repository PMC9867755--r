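test_that("2D Euclidean distance matches the closed form", {
  expect_equal(euclid_2d(c(0, 0), c(3, 4)), 5)
  expect_equal(euclid_2d(c(1, 1), c(1, 1)), 0)
  expect_equal(euclid_2d(c(0, 0), c(1, 1)), sqrt(2))
})

test_that("knn mean distances match hand enumeration on the 3-point fixture", {
  pts <- rbind(c(0, 0), c(3, 4), c(0, 8))
  m <- knn_mean_distance(pts, 1:3, n_max = 2)
  # pairwise distances: 5, 8, 5 -> nearest neighbour of each point is at 5
  expect_equal(unname(m[, 1]), c(5, 5, 5))
  # per-point means over 2 neighbours: (5+8)/2, (5+5)/2, (8+5)/2
  expect_equal(unname(m[, 2]), c(6.5, 5, 6.5))
  expect_equal(mean(m[, 1]), 5)
  expect_equal(mean(m[, 2]), 6)
})

test_that("knn mean distance agrees with the O(N^2) brute-force oracle", {
  withr::local_seed(4)
  pts <- matrix(rnorm(2 * 180), ncol = 2)
  q <- sample(180, 60)
  fast <- knn_mean_distance(pts, q, n_max = 50)
  slow <- brute_knn_mean(pts, q, n_max = 50)
  expect_equal(fast, slow, tolerance = 1e-9)
  # identical points give 0 for every n
  same <- matrix(1, 10, 2)
  expect_true(all(knn_mean_distance(same, n_max = 5) == 0))
  expect_error(knn_mean_distance(pts[1:5, ], n_max = 10), "points")
})

test_that("width curves are non-decreasing in n with a valid envelope", {
  sim <- generate_manifold(synth_config(cells_per_condition_stage = 80L,
                                        seed = 9L))
  cfg <- pipeline_config(n_cells_width = 80L, n_max = 30L, rng_seed = 9L)
  w <- trajectory_width(sim$table, cfg)
  for (co in c("native", "organoid")) {
    s <- w$summary[w$summary$condition == co, ]
    expect_true(all(diff(s$mean) >= -1e-12))
    expect_true(all(s$lo <= s$mean + 1e-12 & s$mean <= s$hi + 1e-12))
    expect_true(all(s$lo >= 0))
  }
  expect_equal(nrow(w$curves), 2L * cfg$width_replicates * 30L)
})

test_that("doubling all coordinates doubles the width curve exactly", {
  sim <- generate_manifold(synth_config(cells_per_condition_stage = 60L,
                                        seed = 10L))
  cfg <- pipeline_config(n_cells_width = 60L, n_max = 20L, rng_seed = 77L)
  w1 <- trajectory_width(sim$table, cfg)
  tab2 <- sim$table
  centroid <- colMeans(tab2$embedding)
  emb2 <- sweep(sweep(tab2$embedding, 2L, centroid, "-") * 2, 2L,
                centroid, "+")
  tab2 <- cell_table(tab2$counts, tab2$gene_ids, tab2$cell_ids,
                     tab2$condition, tab2$stage, tab2$cluster,
                     cell_type = tab2$cell_type, embedding = emb2)
  w2 <- trajectory_width(tab2, cfg)  # same seed -> paired sampling
  expect_equal(w2$curves$mean_distance, 2 * w1$curves$mean_distance,
               tolerance = 1e-12)
})

test_that("identical point sets give matching curves across conditions", {
  # both conditions share one coordinate set -> curves equal within MC error
  withr::local_seed(5)
  pts <- matrix(rnorm(2 * 300), ncol = 2)
  tab <- make_table(matrix(0L, 600, 2),
                    condition = rep(c("native", "organoid"), each = 300),
                    stage = rep(rep(c("I", "II"), each = 150), 2),
                    cluster = rep(1L, 600), cell_type = rep("NE", 600),
                    embedding = rbind(pts, pts))
  cfg <- pipeline_config(n_cells_width = 200L, n_max = 25L,
                         width_replicates = 5L, rng_seed = 13L)
  w <- trajectory_width(tab, cfg)
  s <- w$summary
  rel <- abs(s$mean[s$condition == "native"] -
               s$mean[s$condition == "organoid"]) /
    s$mean[s$condition == "native"]
  expect_lt(max(rel), 0.10)
})

test_that("diversity statistic is exactly 1 for a single-type stage", {
  tab <- make_table(matrix(0L, 40, 2),
                    condition = rep(c("native", "organoid"), each = 20),
                    stage = "I", cluster = 1L, cell_type = "RGC")
  cfg <- pipeline_config(entropy_pairs = 50L, entropy_replicates = 5L,
                         rng_seed = 2L)
  d <- stage_diversity(tab, cfg)
  expect_true(all(d$samples$value == 1))
  expect_equal(nrow(d$samples), 2L * 5L)
})

test_that("diversity mean matches the without-replacement pair probability", {
  # composition {A:2, B:2}: P(same type) = 2 / C(4,2) = 1/3
  tab <- make_table(matrix(0L, 8, 2),
                    condition = rep(c("native", "organoid"), each = 4),
                    stage = "I", cluster = 1L,
                    cell_type = rep(c("RGC", "RGC", "AC", "AC"), 2))
  cfg <- pipeline_config(entropy_pairs = 1000L, entropy_replicates = 100L,
                         rng_seed = 6L)
  d <- stage_diversity(tab, cfg)
  for (co in c("native", "organoid")) {
    v <- d$samples$value[d$samples$condition == co]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 1 / 3), 3 * se + 1e-9)
  }
})

test_that("diversity resampling operates on labels, not storage order", {
  sim <- generate_manifold(synth_config(cells_per_condition_stage = 50L,
                                        seed = 14L))
  cfg <- pipeline_config(entropy_pairs = 200L, entropy_replicates = 10L,
                         rng_seed = 15L)
  d1 <- stage_diversity(sim$table, cfg)
  # permute cells within each condition x stage block: same seed-derived
  # sampling hits the same label multiset
  tab <- sim$table
  perm <- order(tab$condition, tab$stage, runif(tab$n_cells))
  tab2 <- subset_cells(tab, perm)
  d2 <- stage_diversity(tab2, cfg)
  expect_equal(d1$samples$value, d2$samples$value)
})

test_that("insufficient cells are reported by condition and stage", {
  tab <- make_table(matrix(0L, 3, 2),
                    condition = c("native", "native", "organoid"),
                    stage = "I", cluster = 1L, cell_type = "NE")
  expect_error(stage_diversity(tab, pipeline_config(rng_seed = 1L)),
               "organoid.*I|I.*organoid")
})
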
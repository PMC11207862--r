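test_that("K-means recovers well-separated blobs perfectly", {
  d <- blob_data(n_per = 15, sep = 10)
  ga <- kmeans_groups(d$x, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(ga$cluster, d$y), 1.0)
  expect_setequal(unique(ga$cluster), c(0L, 1L))
  expect_length(ga$cluster, 30)
})

test_that("k equal to n gives singleton clusters with zero inertia", {
  d <- blob_data(n_per = 4, sep = 3, seed = 2)
  ga <- kmeans_groups(d$x, k = 8, seed = 1)
  expect_equal(sort(unname(ga$cluster)), 0:7)
  expect_equal(ga$inertia, 0, tolerance = 1e-10)
})

test_that("auto-k picks two clusters for a two-blob geometry", {
  d <- blob_data(n_per = 12, sep = 8, seed = 3)
  ga <- kmeans_groups(d$x, k = "auto", seed = 1)
  expect_equal(ga$k, 2)
  expect_named(ga$silhouette)
  expect_error(kmeans_groups(matrix(1, 10, 3), k = 2), "constant")
})

test_that("assignment is stable under sample reordering with a fixed seed", {
  d <- blob_data(n_per = 10, sep = 6, seed = 4)
  perm <- sample(nrow(d$x))
  g1 <- kmeans_groups(d$x, k = 2, seed = 7)
  g2 <- kmeans_groups(d$x[perm, ], k = 2, seed = 7)
  expect_equal(mclust::adjustedRandIndex(
    g1$cluster[rownames(d$x)], g2$cluster[rownames(d$x)]), 1.0)
})

test_that("heatmap ordering places identical samples adjacently", {
  set.seed(6)
  base <- rpois(12, 10) + 1
  m <- cbind(s1 = base, s2 = rpois(12, 10) + 1, s3 = base,
             s4 = rpois(12, 30) + 1)
  rownames(m) <- sprintf("t%d", 1:12)
  hm <- heatmap_matrix(abundance_table(m))
  ord <- hm$sample_order
  expect_equal(abs(which(ord == "s1") - which(ord == "s3")), 1)
  expect_identical(dim(hm$matrix), dim(m))
})

test_that("block-structured tables keep within-block samples contiguous", {
  set.seed(8)
  b1 <- matrix(rpois(5 * 4, 50), 5, 4)
  b2 <- matrix(rpois(5 * 4, 2), 5, 4)
  m <- rbind(cbind(b1, b2), cbind(b2, b1))
  dimnames(m) <- list(sprintf("t%d", 1:10), sprintf("s%d", 1:8))
  hm <- heatmap_matrix(abundance_table(m))
  pos <- match(sprintf("s%d", 1:8), hm$sample_order)
  expect_true(max(pos[1:4]) < min(pos[5:8]) || min(pos[1:4]) > max(pos[5:8]))
})

test_that("group comparison handles identity, exact ties and separation", {
  id <- compare_groups(matrix(rep(c(1, 2, 3, 1, 2, 3), 1), nrow = 1),
                       rep(c("A", "B"), each = 3), method = "mann-whitney")
  expect_equal(id$p, 1.0)

  sep <- compare_groups(matrix(c(0, 0, 0, 0, 5, 5, 5, 5), nrow = 1),
                        rep(c("A", "B"), each = 4), method = "mann-whitney")
  expect_equal(sep$p, 2 / 70, tolerance = 1e-12)
  expect_equal(sep$direction, "B>A")

  # zero-variance group falls back from Welch to Mann-Whitney
  expect_message(
    fb <- compare_groups(matrix(c(1, 1, 1, 2, 3, 4), nrow = 1),
                         rep(c("A", "B"), each = 3)),
    "Mann-Whitney")
  expect_equal(fb$method, "mann-whitney")
})

test_that("exact Mann-Whitney agrees with wilcox.test when there are no ties", {
  set.seed(9)
  x <- rnorm(6); y <- rnorm(5) + 0.5
  p_pkg <- compare_groups(matrix(c(x, y), nrow = 1),
                          rep(c("A", "B"), c(6, 5)),
                          method = "mann-whitney")$p
  p_ref <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("planted differential taxa are detected with the right direction", {
  cfg <- simulation_config(n_taxa = 200, overdispersion = 2000, seed = 5)
  sim <- simulate_dataset(cfg)
  rel <- to_relative_abundance(sim$table)$values
  res <- compare_groups(rel, sim$truth$group)
  truth <- sim$truth$characteristic_taxa
  hits <- res[match(truth$taxon_id, res$feature), ]
  expect_gt(mean(hits$p_adj < 0.05), 0.85)
  agree <- substr(hits$direction, 1, 1) == truth$direction
  expect_gt(mean(agree[hits$p_adj < 0.05]), 0.95)
})

test_that("null p-values are uniform and BH is monotone", {
  set.seed(10)
  vals <- matrix(rnorm(1000 * 20), 1000, 20)
  res <- compare_groups(vals, rep(c("A", "B"), each = 10))
  ks <- ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})
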
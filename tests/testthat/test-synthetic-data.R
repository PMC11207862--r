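test_that("default simulation has the configured shape and is deterministic", {
  sim <- simulate_dataset(simulation_config(seed = 1))
  expect_identical(dim(sim$table), c(745L, 44L))
  expect_equal(as.numeric(table(sim$metadata$group)), c(31, 13))
  expect_identical(nrow(sim$truth$characteristic_taxa), 23L)
  expect_equal(sum(sim$truth$characteristic_taxa$direction == "A"), 19)

  sim2 <- simulate_dataset(simulation_config(seed = 1))
  expect_identical(sim$table$values, sim2$table$values)
  expect_identical(sim$metadata, sim2$metadata)

  sim3 <- simulate_dataset(simulation_config(seed = 2))
  expect_false(identical(sim$table$values, sim3$table$values))
})

test_that("planted enrichment shows in group means at strong effect", {
  cfg <- simulation_config(n_taxa = 120, group_sizes = c(A = 20, B = 20),
                           n_characteristic = 10, n_enriched_in_A = 7,
                           log2_effect = 3, overdispersion = 5000, seed = 4)
  sim <- simulate_dataset(cfg)
  rel <- to_relative_abundance(sim$table)$values
  grp <- sim$truth$group
  truth <- sim$truth$characteristic_taxa
  for (i in seq_len(nrow(truth))) {
    mA <- mean(rel[truth$taxon_id[i], grp == "A"])
    mB <- mean(rel[truth$taxon_id[i], grp == "B"])
    if (truth$direction[i] == "A") expect_gt(mA, mB) else expect_lt(mA, mB)
  }
})

test_that("phenotypes land in their configured per-group ranges", {
  sim <- simulate_dataset(simulation_config(seed = 3))
  md <- sim$metadata
  cfg <- simulation_config()
  for (g in c("A", "B")) {
    sub <- md[md$group == g, ]
    for (v in names(cfg$nutrient_ranges[[g]])) {
      rng <- cfg$nutrient_ranges[[g]][[v]]
      pad <- diff(rng) * 0.5   # latent tails may overshoot modestly
      expect_true(all(sub[[v]] > rng[1] - pad & sub[[v]] < rng[2] + pad),
                  label = paste(g, v, "within padded range"))
    }
  }
  # group A phenotypes exceed group B on average, as configured
  for (v in c("available_N", "available_P", "available_K",
              "polyphenols", "theanine", "caffeine")) {
    expect_gt(mean(md[[v]][md$group == "A"]), mean(md[[v]][md$group == "B"]))
  }
})

test_that("with vanishing path strength the taxa-nutrient link disappears", {
  # within one group, so the per-group range midpoints (which differ by
  # design) do not re-introduce a correlation through the group channel
  rs <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_taxa = 150, path_strength = 0.01, seed = s)
    sim <- simulate_dataset(cfg)
    a <- sim$metadata$group == "A"
    abs(cor(sim$truth$taxon_load[a], sim$metadata$available_N[a]))
  }, numeric(1))
  expect_lt(mean(rs), 0.2)

  # at full strength the within-group link is strong
  sim <- simulate_dataset(simulation_config(n_taxa = 150, path_strength = 1,
                                            seed = 3))
  a <- sim$metadata$group == "A"
  expect_gt(cor(sim$truth$taxon_load[a], sim$metadata$available_N[a]), 0.6)
})

test_that("simulated column sums equal the drawn depths exactly", {
  cfg <- simulation_config(n_taxa = 60, group_sizes = c(A = 6, B = 5),
                           n_characteristic = 4, n_enriched_in_A = 3,
                           sequencing_depth = 2000, seed = 9)
  sim <- simulate_dataset(cfg)
  expect_identical(unname(colSums(sim$table$values)),
                   as.numeric(sim$truth$depths))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_characteristic = 30, n_taxa = 20), "<=")
  expect_error(simulation_config(sequencing_depth = 0), "depth")
  expect_error(simulation_config(overdispersion = 0), "Dirichlet")
  expect_error(simulation_config(path_strength = 0), "path_strength")
})

test_that("subsampling is a faithful hypergeometric draw", {
  t0 <- random_count_table(6, 3, seed = 2)
  full <- subsample_reads(t0, min(colSums(t0$values)), seed = 1)
  expect_equal(unname(colSums(full$values)),
               rep(min(colSums(t0$values)), 3))
  same_depth <- subsample_reads(t0, 0, seed = 1)
  expect_true(all(same_depth$values == 0))

  # depth equal to a column's total returns that column unchanged
  one <- abundance_table(matrix(c(4, 6), 2, 1,
                                dimnames = list(c("a", "b"), "s1")))
  expect_equal(subsample_reads(one, 10, seed = 1)$values, one$values)

  expect_error(subsample_reads(one, 11), "exceeds total reads.*s1")

  # mean of the first taxon over many draws matches the expectation 2.5
  two <- abundance_table(matrix(c(5, 5), 2, 1,
                                dimnames = list(c("a", "b"), "s1")))
  set.seed(42)
  draws <- replicate(10000, subsample_reads(two, 5)$values[1, 1])
  expect_lt(abs(mean(draws) - 2.5), 0.05)
})
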
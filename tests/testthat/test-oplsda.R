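test_that("an informative variable dominates a noise background", {
  # n large relative to the 10 noise variables so the single predictive
  # component is not diluted by chance correlations
  d <- construction_dataset(n = 400, p_noise = 10)
  m <- fit_oplsda(d$x, d$y, n_ortho = 0)
  expect_gt(m$R2Y, 0.95)
  expect_identical(names(which.max(m$vip)), "info")
  expect_gt(m$Q2, 0.9)
  expect_gte(m$R2Y, m$Q2)

  d40 <- construction_dataset(n = 40, p_noise = 10)
  m40 <- fit_oplsda(d40$x, d40$y, n_ortho = 0)
  expect_identical(names(which.max(m40$vip)), "info")
  expect_gt(m40$R2Y, 0.8)
})

test_that("a single perfectly separating variable has VIP exactly 1", {
  x <- matrix(c(rep(0, 5), rep(3, 5)) + rnorm(10, 0, 0.01), ncol = 1,
              dimnames = list(NULL, "v1"))
  m <- fit_oplsda(x, rep(c("A", "B"), each = 5), n_ortho = 0)
  expect_equal(unname(m$vip), 1.0, tolerance = 1e-12)
})

test_that("VIP normalisation and score orthogonality hold exactly", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 24; p <- 15
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c("A", "B"), each = n / 2)
    x[, 1] <- x[, 1] + ifelse(y == "A", 1.5, -1.5)
    x[, 2] <- x[, 2] + rnorm(n, 0, 3)   # structured noise for ortho removal
    m <- fit_oplsda(x, y, n_ortho = 2)
    expect_equal(mean(m$vip^2), 1.0, tolerance = 1e-8)
    if (m$n_ortho > 0)
      for (j in seq_len(m$n_ortho))
        expect_lt(abs(cor(m$scores, m$ortho_scores[, j])), 1e-8)
  }
})

test_that("cross-validated Q2 never exceeds in-sample R2Y", {
  set.seed(12)
  for (rep in 1:50) {
    n <- 14 + 2 * (rep %% 4); p <- 5 + (rep %% 7)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c("A", "B"), length.out = n)
    m <- fit_oplsda(x, y, n_ortho = 0)
    expect_gte(m$R2Y, m$Q2)
  }
})

test_that("permuted labels destroy predictability", {
  d <- construction_dataset(n = 40, p_noise = 10, seed = 2)
  q2 <- vapply(1:20, function(s) {
    set.seed(s + 100)
    fit_oplsda(d$x, sample(d$y), n_ortho = 0)$Q2
  }, numeric(1))
  expect_lt(median(q2), 0)
  expect_gte(mean(q2 <= 0.1), 0.9)
  expect_lt(max(q2), 0.3)
})

test_that("permutation test uses the add-one estimator", {
  d <- construction_dataset(n = 20, p_noise = 5, seed = 3)
  pt <- permutation_test(d$x, d$y, n_ortho = 0, n_perm = 20, seed = 1)
  expect_equal(pt$p_Q2, 1 / 21, tolerance = 1e-12)
  expect_equal(pt$p_R2Y, 1 / 21, tolerance = 1e-12)
  expect_length(pt$permuted_Q2, 20)
  expect_warning(permutation_test(d$x, d$y, n_ortho = 0, n_perm = 10),
                 "resolution")
})

test_that("S-plot separates informative from noise variables", {
  d <- construction_dataset(n = 200, p_noise = 8, seed = 4)
  m <- fit_oplsda(d$x, d$y, n_ortho = 0)
  sp <- splot(m, d$x)
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-12))
  info <- sp[sp$taxon == "info", ]
  expect_gt(abs(info$pcorr1), 0.9)
  expect_true(all(abs(sp$pcorr1[sp$taxon != "info"]) < 0.3))
  nz <- abs(sp$p1) > 1e-9 & abs(sp$pcorr1) > 1e-9
  expect_true(all(sign(sp$p1[nz]) == sign(sp$pcorr1[nz])))
})

test_that("VIP screening ranks and thresholds correctly", {
  d <- construction_dataset(n = 30, p_noise = 6, seed = 5)
  m <- fit_oplsda(d$x, d$y, n_ortho = 0)
  all_taxa <- screen_key_taxa(m, threshold = 0)
  expect_setequal(all_taxa, colnames(d$x))
  expect_identical(all_taxa[1], "info")
  expect_identical(all_taxa, names(sort(m$vip, decreasing = TRUE)))
  high <- screen_key_taxa(m, threshold = max(m$vip) - 1e-9)
  expect_identical(high, "info")
})

test_that("zero-variance variables are dropped with a warning", {
  d <- construction_dataset(n = 20, p_noise = 4, seed = 6)
  x <- cbind(d$x, flat = rep(2, 20))
  expect_warning(m <- fit_oplsda(x, d$y, n_ortho = 0), "zero-variance")
  expect_false("flat" %in% names(m$vip))
  expect_error(fit_oplsda(d$x, rep("A", 20)), "two classes")
})

test_that("auto selection degrades to plain PLS-DA without orthogonal structure", {
  # one variable leaves no y-orthogonal subspace at all
  set.seed(7)
  y <- rep(c("A", "B"), each = 10)
  x <- matrix(ifelse(y == "A", 1, -1) + rnorm(20, 0, 0.1), ncol = 1,
              dimnames = list(NULL, "v"))
  m <- fit_oplsda(x, y, n_ortho = "auto")
  expect_identical(m$n_ortho, 0)
  expect_identical(fit_oplsda(x, y, n_ortho = 3)$n_ortho, 0)
})
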
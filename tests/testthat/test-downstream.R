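test_that("RDA proportions behave at the self-explanation and null extremes", {
  set.seed(1)
  Y <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("y", 1:4)))
  r_self <- redundancy_analysis(Y, Y)
  expect_equal(r_self$proportion_constrained, 1.0, tolerance = 1e-8)

  set.seed(2)
  Yb <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, paste0("y", 1:3)))
  Xb <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, paste0("x", 1:2)))
  r_null <- redundancy_analysis(Yb, Xb)
  expect_lt(r_null$proportion_constrained, 0.05)
  expect_lte(r_null$rank, 2)
  expect_true(all(diff(r_null$eigenvalues_constrained) <= 1e-12))
})

test_that("RDA constrained proportion is rotation invariant in X", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("y", 1:3)))
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, paste0("x", 1:2)))
  Y[, 1] <- Y[, 1] + X[, 1]
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Xr <- X %*% R; colnames(Xr) <- colnames(X)
  expect_equal(redundancy_analysis(Y, X)$proportion_constrained,
               redundancy_analysis(Y, Xr)$proportion_constrained,
               tolerance = 1e-10)
})

test_that("correlation network recovers exact and near-exact relations", {
  set.seed(4)
  x <- rnorm(50)
  f <- cbind(a = x, b = x, c = -x + rnorm(50, 0, 1e-6), d = rnorm(50))
  net <- correlation_network(f, r_min = 0.6, p_max = 0.05)
  ab <- net$edges[net$edges$node1 == "a" & net$edges$node2 == "b", ]
  expect_equal(ab$r, 1.0, tolerance = 1e-12)
  ac <- net$edges[(net$edges$node1 == "a" & net$edges$node2 == "c"), ]
  expect_lt(ac$r, -0.999)
  expect_identical(ac$sign, "negative")
  expect_false(any(net$edges$node1 == net$edges$node2))
  # r matches the direct two-variable oracle
  for (i in seq_len(nrow(net$edges)))
    expect_equal(net$edges$r[i],
                 cor(f[, net$edges$node1[i]], f[, net$edges$node2[i]]),
                 tolerance = 1e-12)
})

test_that("independent variables produce essentially no edges", {
  n_edges <- vapply(1:20, function(s) {
    set.seed(s)
    f <- matrix(rnorm(200 * 8), 200, 8)
    nrow(correlation_network(f, r_min = 0.5, p_max = 0.05)$edges)
  }, numeric(1))
  expect_lte(sum(n_edges), 1)
})

test_that("zero-variance variables are excluded with a message", {
  set.seed(5)
  f <- cbind(a = rnorm(20), b = rnorm(20), flat = rep(1, 20))
  expect_message(net <- correlation_network(f), "flat")
  expect_false("flat" %in% net$nodes)
})

test_that("a noise-free latent chain recovers unit path coefficients", {
  set.seed(6)
  z <- rnorm(50)
  dat <- cbind(i1 = z * 2 + 1, i2 = z * 0.5 - 3, i3 = z * 4)
  fit <- pls_sem(dat, blocks = list(L1 = "i1", L2 = "i2", L3 = "i3"),
                 paths = list(L2 = "L1", L3 = "L2"), n_boot = 0)
  expect_equal(fit$paths$estimate, c(1, 1), tolerance = 1e-6)
  # single-indicator blocks: latent equals the standardized indicator
  expect_equal(unname(fit$latent_scores[, "L1"]),
               as.numeric(scale(dat[, "i1"])), tolerance = 1e-9)
})

test_that("path coefficients equal standardized OLS slopes for single indicators", {
  set.seed(7)
  x1 <- rnorm(80)
  x2 <- 0.6 * x1 + rnorm(80, 0, 0.8)
  x3 <- -0.5 * x2 + rnorm(80, 0, 0.6)
  dat <- cbind(a = x1, b = x2, c = x3)
  fit <- pls_sem(dat, blocks = list(A = "a", B = "b", C = "c"),
                 paths = list(B = "A", C = "B"), n_boot = 0)
  sab <- coef(lm(scale(x2) ~ scale(x1)))[2]
  sbc <- coef(lm(scale(x3) ~ scale(x2)))[2]
  expect_equal(fit$paths$estimate, unname(c(sab, sbc)), tolerance = 1e-6)
  expect_true(all(abs(colMeans(fit$latent_scores)) < 1e-10))
  expect_equal(unname(apply(fit$latent_scores, 2, sd)), rep(1, 3),
               tolerance = 1e-10)
})

test_that("bootstrap p-values for a true-zero path are not anticonservative", {
  hits <- vapply(1:100, function(s) {
    set.seed(s + 300)
    dat <- cbind(a = rnorm(40), b = rnorm(40))
    fit <- pls_sem(dat, blocks = list(A = "a", B = "b"),
                   paths = list(B = "A"), n_boot = 120, seed = s)
    fit$paths$p[1] <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.08)
})

test_that("cycles and bad blocks are rejected", {
  dat <- cbind(a = rnorm(10), b = rnorm(10))
  expect_error(pls_sem(dat, blocks = list(A = "a", B = "b"),
                       paths = list(A = "B", B = "A"), n_boot = 0), "cyclic")
  expect_error(pls_sem(dat, blocks = list(A = "zz"), paths = list(),
                       n_boot = 0), "missing indicators")
})
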
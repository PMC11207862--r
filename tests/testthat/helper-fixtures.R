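# shared fixture builders

random_count_table <- function(n_taxa = 5, n_samples = 4, seed = 1,
                               lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%d", seq_len(n_taxa)),
                              sprintf("s%d", seq_len(n_samples))))
  abundance_table(m, unit = "counts")
}

# two well-separated Gaussian blobs, samples x features
blob_data <- function(n_per = 15, p = 4, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  rownames(x) <- sprintf("s%d", seq_len(2 * n_per))
  list(x = x, y = rep(c("A", "B"), each = n_per))
}

# one informative variable plus pure-noise variables
construction_dataset <- function(n = 40, p_noise = 10, noise = 0.05,
                                 seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  ynum <- ifelse(y == "A", 1, -1)
  x <- cbind(info = ynum + rnorm(n, 0, noise),
             matrix(rnorm(n * p_noise), n, p_noise,
                    dimnames = list(NULL, sprintf("noise%d", seq_len(p_noise)))))
  list(x = x, y = y)
}

# two classes on disjoint discrete bands ({0,1} vs {5,6}) in every feature:
# separable with a wide margin AND test values coincide with training values,
# so split-based learners that place their boundary at a class's training
# edge still classify every draw correctly
banded_data <- function(n_per = 22, p = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(sample(0:1, n_per * p, TRUE), n_per, p),
             matrix(sample(5:6, n_per * p, TRUE), n_per, p))
  x <- x + 0  # numeric
  rownames(x) <- sprintf("s%d", seq_len(2 * n_per))
  list(x = x, y = rep(c("A", "B"), each = n_per))
}

# small fast harness configuration for tests
tiny_harness <- function(n_iterations = 5, seed = 1,
                         families = c("knn", "svm", "bpnn", "rf", "xgb")) {
  harness_config(
    n_iterations = n_iterations, seed = seed, families = families,
    grids = list(knn = data.frame(k = c(3, 7)),
                 svm = expand.grid(C = c(1, 10), sigma = c(0.01, 0.1)),
                 bpnn = expand.grid(size = 2, decay = 0.1),
                 rf = list(ntree = 100, mtry = 2),
                 xgb = expand.grid(nrounds = 50, max_depth = 3, eta = 0.3,
                                   colsample_bytree = 1, min_child_weight = 1,
                                   subsample = 1)))
}
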
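#' Validation-harness configuration
#'
#' Settings for the repeated stratified-holdout ensemble of five
#' classifiers (KNN, RBF-SVM, single-hidden-layer backprop neural network,
#' random forest, gradient boosting). Defaults follow the conventional
#' protocol: 80/20 stratified splits, 100 randomized iterations, inner
#' stratified 5-fold cross-validation grid tuning; KNN scans k = 1..20,
#' SVM scans C and sigma over decades 1e-3..1e3, the network scans hidden
#' size {2,4,8,16} x weight decay {0, 0.01, 0.1}, the forest keeps 500
#' trees and scans mtry = 1..min(59, p), and boosting uses a compact grid
#' over nrounds, depth, learning rate and sampling ratios.
#'
#' @param train_fraction Training fraction of each split, in (0, 1).
#' @param n_iterations Number of randomized split iterations.
#' @param inner_cv_folds Folds of the inner tuning CV.
#' @param seed Master seed; iteration i uses `seed + i`.
#' @param families Which model families to run.
#' @param grids Named list of tuning grids overriding the defaults
#'   (data frames; `rf` also takes `ntree`).
#' @return A `harness_config` list.
#' @export
harness_config <- function(train_fraction = 0.8, n_iterations = 100,
                           inner_cv_folds = 5, seed = 1,
                           families = c("knn", "svm", "bpnn", "rf", "xgb"),
                           grids = list()) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  defaults <- list(
    knn = data.frame(k = 1:20),
    svm = expand.grid(C = 10^(-3:3), sigma = 10^(-3:3)),
    bpnn = expand.grid(size = c(2, 4, 8, 16), decay = c(0, 0.01, 0.1)),
    rf = list(ntree = 500, mtry = NULL),  # mtry grid resolved per dataset
    xgb = expand.grid(nrounds = c(50, 150), max_depth = c(3, 6),
                      eta = c(0.1, 0.3), colsample_bytree = c(0.6, 1),
                      min_child_weight = c(1, 5), subsample = c(0.8, 1))
  )
  for (f in names(grids)) {
    if (f == "rf") defaults$rf[names(grids$rf)] <- grids$rf
    else defaults[[f]] <- grids[[f]]
  }
  for (f in setdiff(families, "rf"))
    if (nrow(defaults[[f]]) < 1) stop("empty tuning grid for ", f)
  structure(list(train_fraction = train_fraction,
                 n_iterations = n_iterations,
                 inner_cv_folds = inner_cv_folds, seed = seed,
                 families = families, grids = defaults),
            class = "harness_config")
}

# ---- learners ------------------------------------------------------------
# Each learner takes standardized train/test matrices, a factor y with
# levels c(neg, pos), and one grid row; returns predicted labels and a
# class-pos score in [0, 1].

fit_predict_knn <- function(xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  pred <- class::knn(xtr, xte, ytr, k = pars$k, prob = TRUE)
  pwin <- attr(pred, "prob")
  score <- ifelse(pred == pos, pwin, 1 - pwin)
  list(pred = pred, score = score)
}

fit_predict_svm <- function(xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  m <- e1071::svm(x = xtr, y = ytr, kernel = "radial", cost = pars$C,
                  gamma = pars$sigma, scale = FALSE)
  pred <- stats::predict(m, xte, decision.values = TRUE)
  d <- attr(pred, "decision.values")[, 1]
  # decision values are oriented toward the first label in the colname
  first <- strsplit(colnames(attr(pred, "decision.values"))[1], "/")[[1]][1]
  if (first != pos) d <- -d
  list(pred = factor(as.character(pred), levels = levels(ytr)),
       score = stats::plogis(d))
}

fit_predict_bpnn <- function(xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  m <- nnet::nnet(x = xtr, y = as.numeric(ytr == pos), size = pars$size,
                  decay = pars$decay, maxit = 500, entropy = TRUE,
                  trace = FALSE)
  score <- as.numeric(stats::predict(m, xte))
  list(pred = factor(ifelse(score >= 0.5, pos, levels(ytr)[1]),
                     levels = levels(ytr)),
       score = score)
}

fit_predict_rf <- function(xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  m <- randomForest::randomForest(x = xtr, y = ytr, ntree = pars$ntree,
                                  mtry = pars$mtry)
  score <- stats::predict(m, xte, type = "prob")[, pos]
  list(pred = stats::predict(m, xte), score = as.numeric(score))
}

fit_predict_xgb <- function(xtr, ytr, xte, pars) {
  pos <- levels(ytr)[2]
  dtr <- xgboost::xgb.DMatrix(as.matrix(xtr),
                              label = as.numeric(ytr == pos))
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = pars$max_depth,
                  eta = pars$eta, colsample_bytree = pars$colsample_bytree,
                  min_child_weight = pars$min_child_weight,
                  subsample = pars$subsample, nthread = 1),
    data = dtr, nrounds = pars$nrounds, verbose = 0)
  score <- stats::predict(m, xgboost::xgb.DMatrix(as.matrix(xte)))
  list(pred = factor(ifelse(score >= 0.5, pos, levels(ytr)[1]),
                     levels = levels(ytr)),
       score = as.numeric(score))
}

learner_for <- function(family) {
  switch(family,
         knn = fit_predict_knn, svm = fit_predict_svm,
         bpnn = fit_predict_bpnn, rf = fit_predict_rf,
         xgb = fit_predict_xgb,
         stop("unknown model family: ", family))
}

# stratified fold ids (1..k) within each class
stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(k), length(idx))
  }
  id
}

resolve_grid <- function(family, cfg, p) {
  if (family != "rf") return(cfg$grids[[family]])
  g <- cfg$grids$rf
  mtry <- if (is.null(g$mtry)) seq_len(min(59, p)) else g$mtry
  data.frame(ntree = g$ntree, mtry = mtry)
}

# inner stratified k-fold grid search by accuracy; first max wins
tune_family <- function(family, x, y, grid, k) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  learner <- learner_for(family)
  fold <- stratified_folds(y, k)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0
    for (f in seq_len(k)) {
      te <- fold == f
      if (all(te) || length(unique(y[!te])) < 2) next
      out <- learner(x[!te, , drop = FALSE], y[!te],
                     x[te, , drop = FALSE], grid[g, , drop = FALSE])
      correct <- correct + sum(out$pred == y[te])
    }
    correct / length(y)
  }, numeric(1))
  grid[which.max(acc), , drop = FALSE]
}

#' Run the five-classifier validation harness
#'
#' For each of `n_iterations` seeded iterations: draw a stratified
#' train/test split, tune each model family by inner stratified CV on the
#' training split (accuracy criterion), refit the best configuration on the
#' whole training split, and record the test-set predictions and class
#' scores. After all iterations each family's test predictions are pooled
#' (model integration) into one overall confusion matrix and one ROC curve
#' built from the concatenated score/label pairs.
#'
#' Features are standardized per split with training-split statistics.
#' A learner returning non-finite scores has its iteration retried once
#' with a fresh seed, then errors.
#'
#' @param X Samples x features numeric matrix.
#' @param y Two-level class labels (>= 5 samples per class).
#' @param cfg A [harness_config()].
#' @return An `ensemble_result`: per family the pooled confusion matrix,
#'   overall accuracy, pooled ROC/AUC, pooled scores and truth, and the
#'   chosen hyperparameters per iteration.
#' @export
run_ensemble <- function(X, y, cfg = harness_config()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- factor(as.character(y))
  if (nlevels(y) != 2) stop("y must have two classes")
  if (min(table(y)) < 5) stop("need at least 5 samples per class")
  fams <- cfg$families
  pool <- stats::setNames(lapply(fams, function(f)
    list(scores = numeric(0), truth = factor(levels = levels(y)),
         pred = factor(levels = levels(y)), pars = list())), fams)

  run_iteration <- function(i, seed) {
    set.seed(seed)
    te <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_te <- max(1, round((1 - cfg$train_fraction) * length(idx)))
      sample(idx, n_te)
    }))
    tr <- setdiff(seq_len(nrow(X)), te)
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu, "-"), 2, sd_, "/")
    xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu, "-"), 2, sd_, "/")
    out <- list()
    for (f in fams) {
      grid <- resolve_grid(f, cfg, ncol(X))
      best <- tune_family(f, xtr, y[tr], grid, cfg$inner_cv_folds)
      res <- learner_for(f)(xtr, y[tr], xte, best)
      if (any(!is.finite(res$score))) return(NULL)
      out[[f]] <- list(score = res$score, pred = res$pred,
                       truth = y[te], pars = best)
    }
    out
  }

  for (i in seq_len(cfg$n_iterations)) {
    it <- run_iteration(i, cfg$seed + i)
    if (is.null(it)) {
      it <- run_iteration(i, cfg$seed + cfg$n_iterations + i)
      if (is.null(it)) stop("learner produced non-finite scores twice in iteration ", i)
    }
    for (f in fams) {
      pool[[f]]$scores <- c(pool[[f]]$scores, it[[f]]$score)
      pool[[f]]$truth <- factor(c(as.character(pool[[f]]$truth),
                                  as.character(it[[f]]$truth)),
                                levels = levels(y))
      pool[[f]]$pred <- factor(c(as.character(pool[[f]]$pred),
                                 as.character(it[[f]]$pred)),
                               levels = levels(y))
      pool[[f]]$pars[[i]] <- it[[f]]$pars
    }
  }

  families <- lapply(pool, function(p) {
    conf <- table(truth = p$truth, predicted = p$pred)
    roc <- roc_auc(p$scores, p$truth == levels(p$truth)[2])
    list(confusion = conf,
         accuracy = sum(diag(conf)) / sum(conf),
         auc = roc$auc, roc = roc$roc,
         scores = p$scores, truth = p$truth, pred = p$pred,
         chosen_pars = do.call(rbind, p$pars))
  })
  structure(list(families = families, config = cfg,
                 classes = levels(y)), class = "ensemble_result")
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted one half;
#' ROC points by sweeping the distinct score thresholds.
#'
#' @param scores Numeric classifier scores, larger meaning more positive.
#' @param labels Logical (or two-level) truth; `TRUE`/second level is
#'   positive.
#' @return A list with `auc` and a `roc` data frame of (fpr, tpr) points.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last point of each tie block
  tpr <- cumsum(l)[keep] / n1
  fpr <- cumsum(!l)[keep] / n0
  list(auc = auc, roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Feature importance from a tree ensemble
#'
#' Fits one model on the full dataset and extracts its importance scores:
#' mean decrease in node impurity over 500 trees for the random forest,
#' total (fractional) split gain per feature for gradient boosting.
#' Features a boosted model never splits on get importance 0. Deterministic
#' given the seed.
#'
#' @param X Samples x features matrix with column names.
#' @param y Two-level class labels.
#' @param family `"rf"` or `"boosting"`.
#' @param pars Optional named list overriding the fixed fitting
#'   hyperparameters (`ntree`/`mtry` for rf; `nrounds`/`max_depth`/`eta`
#'   for boosting).
#' @param seed Integer seed.
#' @return An `importance_ranking`: `family`, named non-negative `scores`
#'   over all features, and `ranking` (feature ids, most important first,
#'   ties broken by column order).
#' @export
feature_importance <- function(X, y, family = c("rf", "boosting"),
                               pars = list(), seed = 1) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- factor(as.character(y))
  set.seed(seed)
  if (family == "rf") {
    ntree <- pars$ntree %||% 500
    mtry <- pars$mtry %||% max(1, floor(sqrt(ncol(X))))
    m <- randomForest::randomForest(x = X, y = y, ntree = ntree, mtry = mtry,
                                    importance = FALSE)
    sc <- m$importance[, "MeanDecreaseGini"]
    scores <- stats::setNames(as.numeric(sc), rownames(m$importance))
  } else {
    dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y == levels(y)[2]))
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = pars$max_depth %||% 3,
                    eta = pars$eta %||% 0.1, nthread = 1,
                    seed = seed),
      data = dtr, nrounds = pars$nrounds %||% 150, verbose = 0)
    imp <- xgboost::xgb.importance(model = m)
    scores <- stats::setNames(rep(0, ncol(X)), colnames(X))
    scores[imp$Feature] <- imp$Gain
  }
  ranking <- names(scores)[order(-scores, seq_along(scores))]
  structure(list(family = family, scores = scores, ranking = ranking),
            class = "importance_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersection of two top-n importance rankings
#'
#' The characteristic-feature selector: features present in the top `n` of
#' both rankings, ordered by the sum of their two ranks.
#'
#' @param rank_a,rank_b `importance_ranking` objects or plain character
#'   rankings over the same feature universe.
#' @param n Prefix size (default 30).
#' @return Character vector of shared features.
#' @export
top_n_intersection <- function(rank_a, rank_b, n = 30) {
  ra <- if (inherits(rank_a, "importance_ranking")) rank_a$ranking else rank_a
  rb <- if (inherits(rank_b, "importance_ranking")) rank_b$ranking else rank_b
  if (n > length(ra) || n > length(rb))
    stop("n exceeds the length of a ranking")
  if (!setequal(ra, rb)) stop("rankings cover different feature universes")
  shared <- intersect(ra[seq_len(n)], rb[seq_len(n)])
  shared[order(match(shared, ra) + match(shared, rb))]
}

#' Summarize an ensemble run
#'
#' Cross-family arithmetic means of AUC and pooled overall accuracy, at the
#' conventional reporting precision (AUC to 2 decimals, accuracy to 2
#' decimal percent).
#'
#' @param x An `ensemble_result`, or a list with numeric elements `auc`
#'   (fractions) and optionally `accuracy` (percent).
#' @return A list with `per_family` metrics, `mean_auc` and
#'   `mean_overall_accuracy_pct`.
#' @export
summarize_ensemble <- function(x) {
  if (inherits(x, "ensemble_result")) {
    auc <- vapply(x$families, function(f) f$auc, numeric(1))
    acc <- vapply(x$families, function(f) f$accuracy, numeric(1)) * 100
  } else {
    auc <- x$auc
    acc <- x$accuracy %||% NA_real_
  }
  list(per_family = list(auc = auc, accuracy_pct = acc),
       mean_auc = round(mean(auc), 2),
       mean_overall_accuracy_pct = round(mean(acc), 2))
}
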
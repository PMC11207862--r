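#' Orthogonal PLS discriminant analysis
#'
#' Fits a two-class OPLS-DA model: predictor variables are autoscaled
#' (unit variance; Pareto scaling available), the class label is coded
#' +1/-1 and centered, y-orthogonal variation is removed iteratively
#' (Trygg-Wold orthogonal signal correction) and a single predictive PLS
#' component is then fitted by NIPALS. Reported diagnostics are the
#' in-sample goodness of fit `R2Y = 1 - RSS/TSS` and the cross-validated
#' predictability `Q2 = 1 - PRESS/TSS` from 7-fold venetian-blind CV.
#' Variable importance in projection (VIP) is computed on the predictive
#' component, so `mean(VIP^2) = 1` exactly.
#'
#' With `n_ortho = "auto"` orthogonal components are added while the
#' cross-validated Q2 improves by more than 0.01, up to `max_ortho`; with
#' no orthogonal structure the model degrades gracefully to plain PLS-DA
#' (0 orthogonal components).
#'
#' @param X Numeric matrix, samples x variables. Zero-variance variables
#'   are dropped with a warning.
#' @param y Two-level factor/character/numeric class labels (>= 3 samples
#'   per class).
#' @param n_ortho Number of orthogonal components, or `"auto"`.
#' @param scale `"uv"` (autoscaling, default) or `"pareto"`.
#' @param cv_folds Folds for the venetian-blind Q2 (reduced with a message
#'   if it exceeds the sample count).
#' @param max_ortho Cap for the auto scan.
#' @return An object of class `oplsda` with scores, loadings, weights,
#'   `R2Y`, `Q2`, `vip`, scaling parameters and the class coding map.
#' @export
fit_oplsda <- function(X, y, n_ortho = "auto", scale = c("uv", "pareto"),
                       cv_folds = 7, max_ortho = 5) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2) stop("y must have exactly two classes")
  yy <- ifelse(as.character(y) == cls[2], 1, -1)
  if (min(table(yy)) < 3) stop("need at least 3 samples per class")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance variable(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  xm <- colMeans(X)
  xs <- if (scale == "uv") sds else sqrt(sds)
  Xs <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  ym <- mean(yy)
  yc <- yy - ym
  if (cv_folds > nrow(X)) {
    message(sprintf("reducing CV folds from %d to %d", cv_folds, nrow(X)))
    cv_folds <- nrow(X)
  }

  if (identical(n_ortho, "auto")) {
    q2 <- opls_q2(Xs, yc, 0, cv_folds)
    n_ortho <- 0
    while (n_ortho < max_ortho) {
      q2_next <- opls_q2(Xs, yc, n_ortho + 1, cv_folds)
      if (!is.finite(q2_next) || q2_next - q2 <= 0.01) break
      q2 <- q2_next
      n_ortho <- n_ortho + 1
    }
  }
  core <- opls_core(Xs, yc, n_ortho)
  q2 <- opls_q2(Xs, yc, core$n_ortho, cv_folds)
  p_used <- ncol(Xs)
  vip <- sqrt(p_used * core$w^2 / sum(core$w^2))
  names(vip) <- colnames(Xs)

  structure(list(
    scores = core$tp, loadings = core$pp, weights = core$w,
    ortho_scores = core$To, ortho_loadings = core$Po,
    ortho_weights = core$Wo,
    coef_c = core$cc, n_ortho = core$n_ortho,
    R2Y = core$R2Y, Q2 = q2, vip = vip,
    x_center = xm, x_scale = xs, y_mean = ym,
    classes = stats::setNames(c(-1, 1), cls),
    cv_folds = cv_folds, scale = scale
  ), class = "oplsda")
}

# Trygg-Wold O-PLS core on pre-scaled X, centered y
opls_core <- function(Xs, yc, n_ortho) {
  Wo <- Po <- To <- NULL
  Xc <- Xs
  k <- 0
  while (k < n_ortho) {
    w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
    tt <- Xc %*% w
    p <- crossprod(Xc, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    if (sum(wo^2) < 1e-12) break  # no orthogonal variation left
    wo <- wo / sqrt(sum(wo^2))
    to <- Xc %*% wo
    po <- crossprod(Xc, to) / sum(to^2)
    Xc <- Xc - to %*% base::t(po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
    k <- k + 1
  }
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  tp <- Xc %*% w
  pp <- crossprod(Xc, tp) / sum(tp^2)
  cc <- sum(yc * tp) / sum(tp^2)
  yhat <- as.numeric(tp * cc)
  list(w = as.numeric(w), tp = as.numeric(tp), pp = as.numeric(pp), cc = cc,
       Wo = Wo, Po = Po, To = To, n_ortho = k,
       R2Y = 1 - sum((yc - yhat)^2) / sum(yc^2))
}

# predict centered-y values for scaled new data given a fitted core
opls_core_predict <- function(core, Xnew) {
  Xc <- Xnew
  if (core$n_ortho > 0) {
    for (j in seq_len(core$n_ortho)) {
      to <- Xc %*% core$Wo[, j]
      Xc <- Xc - to %*% base::t(core$Po[, j, drop = FALSE])
    }
  }
  as.numeric((Xc %*% core$w) * core$cc)
}

# 7-fold venetian-blind Q2 on pre-scaled data
opls_q2 <- function(Xs, yc, n_ortho, folds) {
  n <- nrow(Xs)
  fold_id <- (seq_len(n) - 1) %% folds + 1
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(sign(yc[tr]))) < 2) next
    # fold models are re-centered locally on the globally-scaled data
    mu <- colMeans(Xs[tr, , drop = FALSE])
    ymu <- mean(yc[tr])
    core_f <- opls_core(sweep(Xs[tr, , drop = FALSE], 2, mu, "-"),
                        yc[tr] - ymu, n_ortho)
    pred <- opls_core_predict(core_f,
                              sweep(Xs[!tr, , drop = FALSE], 2, mu, "-")) + ymu
    press <- press + sum((yc[!tr] - pred)^2)
  }
  1 - press / sum(yc^2)
}

#' Predict from an OPLS-DA model
#'
#' @param object A fitted [fit_oplsda()] model.
#' @param newdata Samples x variables matrix on the original scale.
#' @param ... Unused.
#' @return Data frame with the continuous discriminant score `y_hat`, the
#'   predictive score `t_pred` and the predicted class label.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    colnames(newdata) <- sprintf("V%d", seq_len(ncol(newdata)))
  newdata <- newdata[, names(object$x_center), drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$x_center, "-"), 2, object$x_scale, "/")
  Xc <- Xs
  if (object$n_ortho > 0) {
    for (j in seq_len(object$n_ortho)) {
      to <- Xc %*% object$ortho_weights[, j]
      Xc <- Xc - to %*% base::t(object$ortho_loadings[, j, drop = FALSE])
    }
  }
  tp <- as.numeric(Xc %*% object$weights)
  yhat <- tp * object$coef_c + object$y_mean
  cls <- names(object$classes)
  data.frame(y_hat = yhat, t_pred = tp,
             class = ifelse(yhat >= 0, cls[2], cls[1]),
             stringsAsFactors = FALSE)
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model on `n_perm` random permutations of the class labels and
#' compares the observed R2Y and Q2 with their permutation distributions.
#' P-values use the add-one estimator `(#{permuted >= observed} + 1) /
#' (n_perm + 1)` so they can never be zero; with 200 permutations the
#' attainable minimum is 1/201 ~ 0.005.
#'
#' @param X,y As in [fit_oplsda()].
#' @param n_ortho Orthogonal components; `"auto"` resolves on the observed
#'   labels and the resolved number is then held fixed across permutations.
#' @param n_perm Number of permutations (a warning is issued below 20).
#' @param seed Integer seed.
#' @param cv_folds Folds for Q2.
#' @return A list with observed and permuted R2Y/Q2, `p_R2Y`, `p_Q2`, and
#'   the intercepts of the regression of permuted statistics on the
#'   permuted-to-observed label correlation.
#' @export
permutation_test <- function(X, y, n_ortho = "auto", n_perm = 200, seed = 1,
                             cv_folds = 7) {
  if (n_perm < 20) warning("fewer than 20 permutations: p-value resolution is coarse")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  model <- fit_oplsda(X, y, n_ortho = n_ortho, cv_folds = cv_folds)
  X <- X[, names(model$x_center), drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$x_center, "-"), 2, model$x_scale, "/")
  yy <- model$classes[as.character(y)]
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(yy)
    ypc <- yp - mean(yp)
    core <- opls_core(Xs, ypc, model$n_ortho)
    c(core$R2Y, opls_q2(Xs, ypc, model$n_ortho, model$cv_folds),
      stats::cor(yp, yy))
  }, numeric(3))
  r2p <- perm[1, ]; q2p <- perm[2, ]; rlab <- abs(perm[3, ])
  p_r2 <- (sum(r2p >= model$R2Y) + 1) / (n_perm + 1)
  p_q2 <- (sum(q2p >= model$Q2) + 1) / (n_perm + 1)
  icpt <- function(stat, obs) {
    fit <- stats::lm(c(stat, obs) ~ c(rlab, 1))
    unname(stats::coef(fit)[1])
  }
  list(R2Y = model$R2Y, Q2 = model$Q2,
       permuted_R2Y = r2p, permuted_Q2 = q2p,
       label_correlation = rlab,
       p_R2Y = p_r2, p_Q2 = p_q2,
       intercept_R2Y = icpt(r2p, model$R2Y),
       intercept_Q2 = icpt(q2p, model$Q2),
       n_perm = n_perm, model = model)
}

#' S-plot statistics
#'
#' For every variable, the covariance `p1` of the scaled variable with the
#' predictive score (effect magnitude) and the correlation `pcorr1` with
#' the raw variable (effect reliability); the classic S-plot is `pcorr1`
#' against `p1`, with influential variables (VIP > 1) in its arms.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param X The training matrix the model was fitted on.
#' @return Data frame sorted by `p1`, with columns `taxon`, `p1`, `pcorr1`,
#'   `vip`. Variables with undefined correlation are flagged `excluded`.
#' @export
splot <- function(model, X) {
  stopifnot(inherits(model, "oplsda"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  X <- X[, names(model$x_center), drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$x_center, "-"), 2, model$x_scale, "/")
  tp <- model$scores
  p1 <- as.numeric(crossprod(Xs, tp)) / (nrow(Xs) - 1)
  pcorr1 <- suppressWarnings(as.numeric(stats::cor(X, tp)))
  out <- data.frame(taxon = colnames(X), p1 = p1, pcorr1 = pcorr1,
                    vip = unname(model$vip[colnames(X)]),
                    excluded = !is.finite(pcorr1),
                    stringsAsFactors = FALSE)
  out[order(out$p1), , drop = FALSE]
}

#' Screen key taxa by VIP
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param threshold VIP cut-off; taxa strictly above it are returned,
#'   ranked by descending VIP. The conventional influence cut is 1.
#' @return Character vector of taxon ids.
#' @export
screen_key_taxa <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "oplsda"))
  v <- model$vip[model$vip > threshold]
  names(v)[order(v, decreasing = TRUE)]
}
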
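#' Redundancy analysis
#'
#' Constrained ordination of a multivariate response on explanatory
#' variables: the response matrix is standardized (correlation RDA, since
#' taxa and soil chemistry live on different scales), each response column
#' is regressed on the explanatory matrix, and the fitted and residual
#' covariances are eigen-decomposed into constrained and unconstrained
#' axes. Backed by `vegan::rda`.
#'
#' @param Y Response matrix (samples x response variables).
#' @param X Explanatory matrix (samples x explanatory variables).
#' @return A list with constrained/unconstrained `eigenvalues`,
#'   `proportion_constrained`, `site_scores`, `response_scores`
#'   (species scores), and `biplot_scores` for the explanatory variables.
#' @export
redundancy_analysis <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.data.frame(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must cover the same samples")
  fit <- vegan::rda(Y ~ ., data = X, scale = TRUE)
  eig_c <- fit$CCA$eig
  eig_u <- fit$CA$eig
  list(
    eigenvalues_constrained = as.numeric(eig_c),
    eigenvalues_unconstrained = as.numeric(eig_u),
    proportion_constrained = sum(eig_c) / fit$tot.chi,
    site_scores = vegan::scores(fit, display = "sites",
                                choices = seq_along(eig_c)),
    response_scores = vegan::scores(fit, display = "species",
                                    choices = seq_along(eig_c)),
    biplot_scores = fit$CCA$biplot,
    rank = fit$CCA$rank
  )
}

#' Pairwise correlation network
#'
#' All pairwise Pearson correlations with two-sided t-approximation
#' p-values, Benjamini-Hochberg adjusted within the batch; edges are kept
#' when `|r| >= r_min` and adjusted p `<= p_max`. Zero-variance variables
#' are excluded with a message.
#'
#' @param features Samples x variables matrix (>= 4 samples).
#' @param r_min Minimum absolute correlation (default 0.6).
#' @param p_max Maximum BH-adjusted p (default 0.05).
#' @return A list with `nodes` and an `edges` data frame
#'   (`node1`, `node2`, `r`, `p`, `p_adj`, `sign`).
#' @export
correlation_network <- function(features, r_min = 0.6, p_max = 0.05) {
  features <- as.matrix(features)
  if (nrow(features) < 4) stop("need at least 4 samples")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("V%d", seq_len(ncol(features)))
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) {
    message("excluding zero-variance variable(s): ",
            paste(colnames(features)[sds == 0], collapse = ", "))
    features <- features[, sds > 0, drop = FALSE]
  }
  n <- nrow(features)
  r <- stats::cor(features)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  tv <- rv * sqrt((n - 2) / pmax(1e-300, 1 - rv^2))
  pv <- 2 * stats::pt(-abs(tv), df = n - 2)
  pv[abs(rv) >= 1] <- 0
  padj <- stats::p.adjust(pv, method = "BH")
  keep <- abs(rv) >= r_min & padj <= p_max
  edges <- data.frame(
    node1 = colnames(features)[idx[keep, 1]],
    node2 = colnames(features)[idx[keep, 2]],
    r = rv[keep], p = pv[keep], p_adj = padj[keep],
    sign = ifelse(rv[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = colnames(features), edges = edges)
}

#' PLS path modelling (PLS-SEM)
#'
#' Lohmoeller-style partial least squares path modelling: latent blocks
#' measured by standardized indicators (mode A, correlation outer weights),
#' inner approximation by the centroid scheme, iterated to convergence of
#' the outer weights; path coefficients by OLS of each endogenous latent on
#' its predecessors; bootstrap resampling of samples for standard errors
#' with p-values from the normal approximation. The latent sign is fixed so
#' that the majority of its indicator loadings are positive (indicators
#' expected to load negatively, e.g. taxa enriched in the other group, are
#' accommodated automatically).
#'
#' @param data Samples x indicators data frame or matrix.
#' @param blocks Named list: latent name -> character vector of indicator
#'   columns.
#' @param paths Named list: endogenous latent -> character vector of its
#'   predecessor latents. Must be acyclic.
#' @param n_boot Bootstrap resamples (>= 100 recommended for p-values; 0
#'   skips the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @param max_iter,tol Convergence controls for the outer-weight iteration.
#' @return A `pls_sem` result: `latent_scores` (standardized), `weights`,
#'   `loadings`, a `paths` data frame with estimates, bootstrap SE and p,
#'   and `r_squared` per endogenous latent.
#' @export
pls_sem <- function(data, blocks, paths, n_boot = 500, seed = 1,
                    max_iter = 300, tol = 1e-6) {
  data <- as.matrix(data)
  latents <- names(blocks)
  if (is.null(latents) || any(latents == "")) stop("blocks must be named")
  for (b in latents) {
    miss <- setdiff(blocks[[b]], colnames(data))
    if (length(miss) > 0)
      stop("block '", b, "' references missing indicators: ",
           paste(miss, collapse = ", "))
  }
  if (!all(names(paths) %in% latents) ||
      !all(unlist(paths) %in% latents))
    stop("paths reference unknown latents")
  check_acyclic(paths, latents)

  est <- plspm_estimate(data, blocks, paths, max_iter, tol)

  boot_paths <- NULL
  path_tab <- est$path_table
  if (n_boot > 0) {
    set.seed(seed)
    boot <- matrix(NA_real_, n_boot, nrow(path_tab))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      eb <- try(plspm_estimate(data[idx, , drop = FALSE], blocks, paths,
                               max_iter, tol), silent = TRUE)
      if (!inherits(eb, "try-error")) boot[b, ] <- eb$path_table$estimate
    }
    se <- apply(boot, 2, stats::sd, na.rm = TRUE)
    path_tab$boot_se <- se
    path_tab$p <- 2 * stats::pnorm(-abs(path_tab$estimate) / pmax(se, 1e-12))
    boot_paths <- boot
  }
  structure(list(latent_scores = est$scores, weights = est$weights,
                 loadings = est$loadings, paths = path_tab,
                 r_squared = est$r2, iterations = est$iterations,
                 boot_paths = boot_paths),
            class = "pls_sem")
}

check_acyclic <- function(paths, latents) {
  indeg <- stats::setNames(rep(0L, length(latents)), latents)
  for (e in names(paths)) indeg[e] <- length(paths[[e]])
  remaining <- latents
  repeat {
    src <- remaining[vapply(remaining, function(l) {
      preds <- if (l %in% names(paths)) intersect(paths[[l]], remaining) else character(0)
      length(preds) == 0
    }, logical(1))]
    if (length(src) == 0) {
      if (length(remaining) > 0) stop("cyclic path matrix")
      break
    }
    remaining <- setdiff(remaining, src)
    if (length(remaining) == 0) break
  }
  invisible(TRUE)
}

plspm_estimate <- function(data, blocks, paths, max_iter, tol) {
  latents <- names(blocks)
  Xb <- lapply(blocks, function(cols) {
    m <- scale(data[, cols, drop = FALSE])
    if (any(!is.finite(m))) stop("zero-variance indicator in a block")
    m
  })
  n <- nrow(data)
  # adjacency: connected if either direction of a structural path
  adj <- matrix(FALSE, length(latents), length(latents),
                dimnames = list(latents, latents))
  for (e in names(paths)) for (p in paths[[e]]) {
    adj[e, p] <- TRUE; adj[p, e] <- TRUE
  }
  w <- lapply(Xb, function(m) rep(1, ncol(m)))
  scores <- standardize_scores(Xb, w)
  iterations <- 0
  repeat {
    iterations <- iterations + 1
    # inner approximation, centroid scheme
    Z <- sapply(latents, function(l) {
      nb <- latents[adj[l, ]]
      if (length(nb) == 0) return(scores[, l])
      e <- sign(stats::cor(scores[, l], scores[, nb, drop = FALSE]))
      e[e == 0] <- 1
      as.numeric(scores[, nb, drop = FALSE] %*% as.numeric(e))
    })
    # outer approximation, mode A
    w_new <- lapply(latents, function(l)
      as.numeric(stats::cor(Xb[[l]], Z[, l])))
    names(w_new) <- latents
    delta <- max(unlist(Map(function(a, b) max(abs(abs(a) - abs(b))),
                            w, w_new)))
    w <- w_new
    scores <- standardize_scores(Xb, w)
    if (delta < tol) break
    if (iterations >= max_iter)
      stop("PLS path model failed to converge after ", max_iter,
           " iterations (last delta = ", format(delta), ")")
  }
  # sign convention: majority of loadings positive per latent
  for (l in latents) {
    lo <- as.numeric(stats::cor(Xb[[l]], scores[, l]))
    if (sum(sign(lo)) < 0 || (sum(sign(lo)) == 0 && lo[1] < 0)) {
      scores[, l] <- -scores[, l]
      w[[l]] <- -w[[l]]
    }
  }
  loadings <- lapply(latents, function(l)
    stats::setNames(as.numeric(stats::cor(Xb[[l]], scores[, l])),
                    blocks[[l]]))
  names(loadings) <- latents
  rows <- list(); r2 <- list()
  for (e in names(paths)) {
    preds <- paths[[e]]
    fit <- stats::lm(scores[, e] ~ scores[, preds, drop = FALSE])
    coefs <- stats::coef(fit)[-1]
    rows[[e]] <- data.frame(from = preds, to = e,
                            estimate = as.numeric(coefs),
                            stringsAsFactors = FALSE)
    r2[[e]] <- summary(fit)$r.squared
  }
  list(scores = scores, weights = w, loadings = loadings,
       path_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       r2 = unlist(r2), iterations = iterations)
}

standardize_scores <- function(Xb, w) {
  latents <- names(Xb)
  s <- sapply(latents, function(l) {
    v <- as.numeric(Xb[[l]] %*% w[[l]])
    sdv <- stats::sd(v)
    if (sdv == 0) stop("degenerate latent score for block '", l, "'")
    (v - mean(v)) / sdv
  })
  colnames(s) <- latents
  s
}
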
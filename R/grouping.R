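#' Unsupervised K-means grouping of samples
#'
#' Partitions samples by K-means on z-scored features with 25 random
#' restarts (best inertia kept), using the Hartigan-Wong algorithm: its
#' point-reallocation refinement escapes the poor local minima that plain
#' Lloyd iterations fall into when the informative genera are a small
#' minority of many noisy dimensions. With `k = "auto"` the number of
#' clusters is chosen by scanning k = 2..8 and keeping the k with maximum
#' mean silhouette width (Euclidean).
#'
#' @param features Numeric matrix, samples in rows, variables in columns
#'   (e.g. the transposed relative-abundance matrix).
#' @param k Integer number of clusters, or `"auto"`.
#' @param seed Integer seed governing restarts.
#' @param n_start Number of random restarts.
#' @param standardize Z-score columns first (default TRUE) so
#'   high-abundance genera do not dominate the distances.
#' @return A list of class `group_assignment`: `cluster` (named labels
#'   `0..k-1`), `k`, `inertia`, `silhouette` (per scanned k, when auto),
#'   `centers`, `seed`.
#' @export
kmeans_groups <- function(features, k = 2, seed = 1, n_start = 25,
                          standardize = TRUE) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("S%03d", seq_len(nrow(features)))
  if (standardize) {
    sds <- apply(features, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep)) stop("constant feature matrix: nothing to cluster on")
    features <- scale(features[, keep, drop = FALSE])
  }
  run_k <- function(kk) {
    if (kk > nrow(features)) stop("k exceeds the number of samples")
    set.seed(seed)
    if (kk == nrow(features))   # every sample its own cluster
      return(list(cluster = seq_len(kk), tot.withinss = 0,
                  centers = features))
    stats::kmeans(features, centers = kk, nstart = n_start,
                  iter.max = 100, algorithm = "Hartigan-Wong")
  }
  sil <- NULL
  if (identical(k, "auto")) {
    ks <- 2:min(8, nrow(features) - 1)
    if (length(ks) < 1 || ks[1] < 2) stop("auto scan needs at least 3 samples")
    sil <- vapply(ks, function(kk) {
      fit <- run_k(kk)
      mean(cluster::silhouette(fit$cluster, stats::dist(features))[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  fit <- suppressWarnings(run_k(k))
  structure(list(
    cluster = stats::setNames(fit$cluster - 1L, rownames(features)),
    k = k, inertia = fit$tot.withinss, silhouette = sil,
    centers = fit$centers, seed = seed
  ), class = "group_assignment")
}

#' Dissimilarity-ordered heatmap matrix
#'
#' Orders samples by average-linkage hierarchical clustering on Bray-Curtis
#' dissimilarity and taxa by average linkage on correlation distance
#' (1 - r), and row-z-scores the values for display. This is the matrix
#' behind the usual clustered abundance heatmaps; no graphics are drawn.
#'
#' @param t An [abundance_table()].
#' @param groups Optional `group_assignment`; retained in the output for
#'   annotation.
#' @return A list with `matrix` (row-z-scored, reordered), `taxon_order`,
#'   `sample_order`, and the two `hclust` trees.
#' @export
heatmap_matrix <- function(t, groups = NULL) {
  stopifnot(inherits(t, "abundance_table"))
  if (nrow(t$values) < 2 || ncol(t$values) < 2)
    stop("need at least 2 taxa and 2 samples")
  rel <- to_relative_abundance(t)$values
  samp_d <- vegan::vegdist(base::t(rel), method = "bray")
  samp_h <- stats::hclust(samp_d, method = "average")
  keep <- apply(rel, 1, stats::sd) > 0
  relk <- rel[keep, , drop = FALSE]
  taxa_d <- stats::as.dist(1 - suppressWarnings(stats::cor(base::t(relk))))
  taxa_d[is.na(taxa_d)] <- 1
  taxa_h <- stats::hclust(taxa_d, method = "average")
  z <- base::t(scale(base::t(relk)))
  ord_t <- rownames(relk)[taxa_h$order]
  ord_s <- colnames(rel)[samp_h$order]
  list(matrix = z[ord_t, ord_s, drop = FALSE],
       taxon_order = ord_t, sample_order = ord_s,
       sample_tree = samp_h, taxon_tree = taxa_h,
       groups = if (!is.null(groups)) groups$cluster[ord_s] else NULL)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments;
# tie-safe because it permutes the observed (tied) ranks directly
exact_mw_p <- function(x, y) {
  v <- c(x, y); r <- rank(v)
  n1 <- length(x)
  combs <- utils::combn(length(v), n1)
  obs <- sum(r[seq_len(n1)])
  sums <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

#' Two-group comparison of a feature batch
#'
#' Tests each feature (row) for a location difference between the two
#' groups: Welch's t-test by default or Mann-Whitney, with
#' Benjamini-Hochberg adjustment across the batch and a direction call from
#' the group means. A feature with zero variance in a group falls back from
#' Welch to Mann-Whitney automatically. The Mann-Whitney p is exact (tie-safe
#' enumeration) when both groups have eight or fewer samples, otherwise the
#' normal approximation with tie correction is used.
#'
#' @param values Numeric matrix (features x samples) or a vector for a
#'   single feature.
#' @param groups Two-level factor/character vector over the samples.
#' @param method `"welch"` (default) or `"mann-whitney"`.
#' @return Data frame with columns `feature`, `mean_A`, `mean_B`, `stat`,
#'   `p`, `p_adj`, `direction`, `method`.
#' @export
compare_groups <- function(values, groups, method = c("welch", "mann-whitney")) {
  method <- match.arg(method)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1,
                                             dimnames = list("feature_1", NULL))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  ia <- groups == lev[1]; ib <- groups == lev[2]
  if (sum(ia) < 2 || sum(ib) < 2) stop("need at least 2 samples per group")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%d", seq_len(nrow(values)))

  one <- function(v) {
    a <- v[ia]; b <- v[ib]
    m <- method
    if (m == "welch" && (stats::sd(a) == 0 || stats::sd(b) == 0)) {
      m <- "mann-whitney"
      message("zero variance in a group; falling back to Mann-Whitney")
    }
    if (m == "welch") {
      tt <- stats::t.test(a, b)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      if (max(sum(ia), sum(ib)) <= 8) {
        p <- exact_mw_p(a, b)
        stat <- sum(rank(c(a, b))[seq_along(a)]) -
          length(a) * (length(a) + 1) / 2
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                  correct = TRUE))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
    }
    c(mean(a), mean(b), stat, p, m == "mann-whitney")
  }
  res <- base::t(apply(values, 1, one))
  data.frame(
    feature = rownames(values),
    mean_A = res[, 1], mean_B = res[, 2], stat = res[, 3], p = res[, 4],
    p_adj = stats::p.adjust(res[, 4], method = "BH"),
    direction = ifelse(res[, 1] > res[, 2],
                       paste0(lev[1], ">", lev[2]),
                       paste0(lev[2], ">", lev[1])),
    method = ifelse(res[, 5] == 1, "mann-whitney", "welch"),
    stringsAsFactors = FALSE, row.names = NULL)
}
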
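#' Alpha diversity of one sample
#'
#' Computes observed richness, Shannon entropy (natural log), Gini-Simpson
#' diversity `1 - sum(p^2)`, and the Chao1 richness estimator
#' `S_obs + F1^2 / (2 F2)` from singleton (`F1`) and doubleton (`F2`)
#' counts, with the bias-corrected fallback `S_obs + F1 (F1 - 1) / 2` when
#' no doubletons are present.
#'
#' @param counts Non-negative count vector for a single sample. Shannon and
#'   Simpson tolerate non-integer (e.g. relative) input; Chao1 requires
#'   integer counts and is `NA` otherwise.
#' @return A list with `observed_richness`, `shannon`, `simpson`, `chao1`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  shannon <- -sum(p * log(p))
  simpson <- 1 - sum(p^2)
  s_obs <- sum(counts > 0)
  integerish <- all(abs(counts - round(counts)) < 1e-9)
  chao1 <- if (!integerish) NA_real_ else {
    f1 <- sum(round(counts) == 1)
    f2 <- sum(round(counts) == 2)
    if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  }
  list(observed_richness = s_obs, shannon = shannon,
       simpson = simpson, chao1 = chao1)
}

#' Per-sample alpha diversity table
#'
#' @param t A counts [abundance_table()].
#' @return Data frame, one row per sample.
#' @export
alpha_diversity_table <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  rows <- lapply(seq_len(ncol(t$values)), function(j)
    as.data.frame(alpha_diversity(t$values[, j])))
  out <- do.call(rbind, rows)
  cbind(data.frame(sample_id = sample_ids(t), stringsAsFactors = FALSE), out)
}

new_curve <- function(x, y, dispersion = NULL) {
  if (any(diff(x) <= 0)) stop("curve x values must be strictly increasing")
  if (any(!is.finite(y))) stop("curve y values must be finite")
  structure(list(x = x, y = y, dispersion = dispersion), class = "rhizo_curve")
}

#' Analytic rarefaction curve
#'
#' Expected richness at subsample depth d,
#' `E[S(d)] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`, the exact
#' mean of the without-replacement (hypergeometric) subsampling model; no
#' Monte Carlo is involved.
#'
#' @param counts Integer count vector for one sample.
#' @param depths Increasing depths, each `<= sum(counts)`.
#' @return A curve object with `x = depths`, `y = expected richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- as.numeric(counts)
  if (any(abs(counts - round(counts)) > 1e-9)) stop("counts must be integers")
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count")
  if (any(depths < 0)) stop("depths must be non-negative")
  counts <- counts[counts > 0]
  y <- vapply(depths, function(d) {
    # lchoose form is stable for large N
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, numeric(1))
  new_curve(as.numeric(depths), y)
}

#' Shannon diversity vs sequencing depth
#'
#' Mean Shannon index over `n_rep` seeded without-replacement subsamples at
#' each depth; flattening of this curve indicates the sample was sequenced
#' deeply enough to capture most of its diversity.
#'
#' @param counts Integer count vector for one sample.
#' @param depths Increasing depths, each `<= sum(counts)`.
#' @param n_rep Subsample replicates per depth.
#' @param seed Integer seed.
#' @return A curve with per-depth mean Shannon and its standard deviation.
#' @export
shannon_depth_curve <- function(counts, depths, n_rep = 10, seed = 1) {
  counts <- as.numeric(counts)
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count")
  set.seed(seed)
  stats_by_depth <- vapply(depths, function(d) {
    if (d == 0) return(c(0, 0))
    sh <- replicate(n_rep, {
      sub <- rarefy_vector(counts, d)
      alpha_diversity(sub)$shannon
    })
    c(mean(sh), stats::sd(sh))
  }, numeric(2))
  new_curve(as.numeric(depths), stats_by_depth[1, ],
            dispersion = stats_by_depth[2, ])
}

#' Rank-abundance curve
#'
#' Relative abundances sorted descending; ties keep taxon order (stable
#' sort), zeros are dropped.
#'
#' @param counts Count (or relative) vector for one sample.
#' @return A curve with `x = rank`, `y = relative abundance`.
#' @export
rank_abundance <- function(counts) {
  counts <- as.numeric(counts)
  if (sum(counts) == 0) stop("all-zero count vector")
  p <- counts / sum(counts)
  p <- p[p > 0]
  p <- p[order(p, decreasing = TRUE)]  # radix order is stable
  new_curve(seq_along(p), p)
}

#' Species accumulation curve
#'
#' Mean cumulative richness of the union of k samples, over `n_perm`
#' random sample orderings, for k = 1..n_samples.
#'
#' @param t An [abundance_table()] with at least two samples.
#' @param n_perm Number of random orderings (>= 1).
#' @param seed Integer seed.
#' @return A curve with `x = samples added`, `y = mean richness`, and the
#'   across-permutation standard deviation as dispersion.
#' @export
species_accumulation <- function(t, n_perm = 100, seed = 1) {
  stopifnot(inherits(t, "abundance_table"))
  n <- ncol(t$values)
  if (n < 2) stop("need at least two samples")
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  present <- t$values > 0
  rich <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, nrow(present))
    for (k in seq_len(n)) {
      seen <- seen | present[, ord[k]]
      rich[p, k] <- sum(seen)
    }
  }
  new_curve(seq_len(n), colMeans(rich), dispersion = apply(rich, 2, stats::sd))
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between samples, computed
#' on relative abundances by default so unequal sequencing depths do not
#' masquerade as community differences.
#'
#' @param t An [abundance_table()] with at least two samples.
#' @param relative Normalise columns first (default TRUE); set FALSE to
#'   compute on raw counts.
#' @return A symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(t, relative = TRUE) {
  stopifnot(inherits(t, "abundance_table"))
  if (ncol(t$values) < 2) stop("need at least two samples")
  if (any(colSums(t$values) == 0))
    stop(sprintf("sample '%s' is all zero",
                 sample_ids(t)[which(colSums(t$values) == 0)[1]]))
  m <- if (relative) to_relative_abundance(t)$values else t$values
  d <- as.matrix(vegan::vegdist(base::t(m), method = "bray"))
  diag(d) <- 0
  d
}
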
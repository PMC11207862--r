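#' Simulation configuration
#'
#' Defines the data-generating conditions emulated by [simulate_dataset()]:
#' a two-group rhizosphere community of 44 samples (31 in group A, 13 in
#' group B) over 745 genera, of which 23 are planted "characteristic" genera
#' (19 enriched in group A, 4 enriched in group B) with a two-fold-scale
#' log2 effect, plus chained soil-nutrient and leaf-quality phenotypes whose
#' per-group ranges follow the published field measurements.
#'
#' Counts are Dirichlet-multinomial: per-sample depths are
#' Poisson(`sequencing_depth`), per-sample genus proportions are drawn from
#' Dirichlet(`overdispersion` x group profile). Base proportions follow a
#' power law in abundance rank (`rank_exponent`) to mimic the steep
#' rank-abundance curves of soil communities. Characteristic genera are
#' drawn from abundance ranks `characteristic_ranks`; in group A their base
#' proportions are multiplied by `2^(+log2_effect)` (enriched) or
#' `2^(-log2_effect)` (depleted) before renormalisation.
#'
#' Nutrients are the group-range midpoint plus `path_strength` times the
#' standardized characteristic-taxon load, scaled into the group's range,
#' plus Gaussian noise; quality indexes are the analogous function of the
#' nutrients (not of the taxa directly), giving the chained
#' taxa -> nutrients -> quality structure that the path-modelling stage is
#' expected to recover.
#'
#' @param n_taxa,group_sizes,n_characteristic,n_enriched_in_A Community shape.
#' @param log2_effect Planted log2 abundance effect (> 0).
#' @param sequencing_depth Mean reads per sample (Poisson).
#' @param overdispersion Dirichlet total concentration; smaller = noisier
#'   communities.
#' @param rank_exponent Power-law exponent of the base rank-abundance curve.
#' @param characteristic_ranks Abundance-rank window the planted genera are
#'   sampled from.
#' @param nutrient_ranges,quality_ranges Per-group named lists of `c(lo, hi)`
#'   ranges (mg/kg).
#' @param path_strength Strength in (0, 1] of the taxa -> nutrient and
#'   nutrient -> quality couplings.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 745,
                              group_sizes = c(A = 31, B = 13),
                              n_characteristic = 23,
                              n_enriched_in_A = 19,
                              log2_effect = 1.6,
                              sequencing_depth = 50000,
                              overdispersion = 1000,
                              rank_exponent = 0.9,
                              characteristic_ranks = c(5, 150),
                              nutrient_ranges = list(
                                A = list(available_N = c(30.52, 96.38),
                                         available_P = c(4.95, 12.03),
                                         available_K = c(60.25, 107.32)),
                                B = list(available_N = c(20.19, 40.08),
                                         available_P = c(3.49, 6.02),
                                         available_K = c(30.24, 68.13))),
                              quality_ranges = list(
                                A = list(polyphenols = c(30.31, 36.90),
                                         theanine = c(2.94, 4.73),
                                         caffeine = c(3.02, 5.40)),
                                B = list(polyphenols = c(23.60, 28.93),
                                         theanine = c(2.42, 2.91),
                                         caffeine = c(2.75, 3.13))),
                              path_strength = 0.8,
                              seed = 1) {
  cfg <- list(n_taxa = n_taxa, group_sizes = group_sizes,
              n_characteristic = n_characteristic,
              n_enriched_in_A = n_enriched_in_A, log2_effect = log2_effect,
              sequencing_depth = sequencing_depth,
              overdispersion = overdispersion, rank_exponent = rank_exponent,
              characteristic_ranks = characteristic_ranks,
              nutrient_ranges = nutrient_ranges,
              quality_ranges = quality_ranges,
              path_strength = path_strength, seed = seed)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (length(group_sizes) != 2 || any(group_sizes < 1))
      stop("group_sizes must be two positive counts")
    if (n_enriched_in_A > n_characteristic || n_characteristic > n_taxa)
      stop("need n_enriched_in_A <= n_characteristic <= n_taxa")
    if (log2_effect <= 0) stop("log2_effect must be > 0")
    if (sequencing_depth <= 0) stop("sequencing depth must be positive")
    if (overdispersion <= 0) stop("degenerate Dirichlet: overdispersion must be > 0")
    if (path_strength <= 0 || path_strength > 1)
      stop("path_strength must be in (0, 1]")
    for (rng in c(nutrient_ranges$A, nutrient_ranges$B,
                  quality_ranges$A, quality_ranges$B))
      if (rng[1] >= rng[2]) stop("range lo must be < hi")
  })
  invisible(cfg)
}

# scale a standardized latent into a (lo, hi) range around the midpoint
range_value <- function(z, rng, noise, path_strength) {
  mid <- mean(rng); half <- diff(rng) / 2
  mid + half * 0.45 * (path_strength * z + noise)
}

#' Simulate an abundance table with planted structure
#'
#' Draws a Dirichlet-multinomial genus count table for two sample groups,
#' plus chained nutrient and quality phenotypes, and returns the ground
#' truth used by recovery tests. See [simulation_config()] for the model.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `table` (counts [abundance_table()]), `metadata`
#'   ([sample_metadata()]) and `truth` (characteristic taxa with direction,
#'   true group labels, latent loads).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  n <- sum(cfg$group_sizes)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  sids <- sprintf("S%02d", seq_len(n))
  tids <- sprintf("genus_%04d", seq_len(cfg$n_taxa))

  base <- seq_len(cfg$n_taxa)^(-cfg$rank_exponent)
  base <- base / sum(base)

  lo <- max(1, cfg$characteristic_ranks[1])
  hi <- min(cfg$n_taxa, cfg$characteristic_ranks[2])
  char_idx <- sample(lo:hi, cfg$n_characteristic)
  direction <- rep(c("A", "B"),
                   c(cfg$n_enriched_in_A,
                     cfg$n_characteristic - cfg$n_enriched_in_A))

  prof <- list(A = base, B = base)
  mult <- ifelse(direction == "A", 2^cfg$log2_effect, 2^(-cfg$log2_effect))
  prof$A[char_idx] <- prof$A[char_idx] * mult
  prof$A <- prof$A / sum(prof$A)

  depths <- stats::rpois(n, cfg$sequencing_depth)
  counts <- matrix(0L, cfg$n_taxa, n, dimnames = list(tids, sids))
  for (s in seq_len(n)) {
    alpha <- cfg$overdispersion * prof[[groups[s]]]
    g <- stats::rgamma(cfg$n_taxa, shape = alpha)
    p <- g / sum(g)
    counts[, s] <- stats::rmultinom(1, depths[s], p)[, 1]
  }
  tab <- abundance_table(counts, unit = "counts")

  rel <- sweep(counts, 2, colSums(counts), "/")
  idx_A <- char_idx[direction == "A"]
  idx_B <- char_idx[direction == "B"]
  load <- colSums(rel[idx_A, , drop = FALSE]) -
    colSums(rel[idx_B, , drop = FALSE])
  load_z <- as.numeric(scale(load))

  nut_vars <- names(cfg$nutrient_ranges$A)
  nut <- sapply(nut_vars, function(v) {
    noise <- stats::rnorm(n, 0, sqrt(max(0, 1 - cfg$path_strength^2)))
    vapply(seq_len(n), function(s) {
      range_value(load_z[s], cfg$nutrient_ranges[[groups[s]]][[v]],
                  noise[s], cfg$path_strength)
    }, numeric(1))
  })
  nut <- pmax(nut, 0)
  nut_z <- as.numeric(scale(rowMeans(scale(nut))))

  qual_vars <- names(cfg$quality_ranges$A)
  qual <- sapply(qual_vars, function(v) {
    noise <- stats::rnorm(n, 0, sqrt(max(0, 1 - cfg$path_strength^2)))
    vapply(seq_len(n), function(s) {
      range_value(nut_z[s], cfg$quality_ranges[[groups[s]]][[v]],
                  noise[s], cfg$path_strength)
    }, numeric(1))
  })
  qual <- pmax(qual, 0)

  md <- sample_metadata(data.frame(
    sample_id = sids, group = groups, nut, qual,
    stringsAsFactors = FALSE, check.names = FALSE))

  truth <- list(
    characteristic_taxa = data.frame(taxon_id = tids[char_idx],
                                     direction = direction,
                                     stringsAsFactors = FALSE),
    group = stats::setNames(groups, sids),
    depths = stats::setNames(depths, sids),
    taxon_load = stats::setNames(load_z, sids),
    nutrient_load = stats::setNames(nut_z, sids)
  )
  list(table = tab, metadata = md, truth = truth)
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample column to exactly `depth` reads without
#' replacement (multivariate hypergeometric draw), the resampling model
#' underlying rarefaction analyses.
#'
#' @param t A counts [abundance_table()].
#' @param depth Target reads per sample; must not exceed any column total.
#' @param seed Optional integer seed.
#' @return A counts [abundance_table()] whose columns each sum to `depth`.
#' @export
subsample_reads <- function(t, depth, seed = NULL) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$unit != "counts") stop("subsampling requires a counts table")
  if (depth < 0 || depth != round(depth)) stop("depth must be a non-negative integer")
  cs <- colSums(t$values)
  short <- which(cs < depth)
  if (length(short) > 0)
    stop(sprintf("depth %d exceeds total reads (%d) of sample '%s'",
                 as.integer(depth), as.integer(cs[short[1]]),
                 sample_ids(t)[short[1]]))
  if (!is.null(seed)) set.seed(seed)
  out <- apply(t$values, 2, rarefy_vector, depth = depth)
  dimnames(out) <- dimnames(t$values)
  abundance_table(out, unit = "counts")
}

# sequential conditional hypergeometric draw of `depth` reads from `counts`
rarefy_vector <- function(counts, depth) {
  counts <- as.numeric(counts)
  n_left <- sum(counts)
  k_left <- depth
  out <- numeric(length(counts))
  for (i in seq_along(counts)) {
    if (k_left == 0) break
    n_left <- n_left - counts[i]
    if (n_left <= 0) { out[i] <- k_left; k_left <- 0; break }
    x <- stats::rhyper(1, counts[i], n_left, k_left)
    out[i] <- x
    k_left <- k_left - x
  }
  out
}
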
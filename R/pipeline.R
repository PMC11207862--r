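#' Pipeline configuration
#'
#' One configuration object driving [run_pipeline()]: either a simulation
#' preset or input file paths, stage toggles, nested module settings and a
#' master seed. Can be loaded from YAML.
#'
#' @param input `"simulate"` (default) to draw data from
#'   [simulate_dataset()], or a list with `table` and `metadata` file paths.
#' @param stages Character vector of stages to run, in dependency order a
#'   subset of `c("diversity", "cluster", "screen", "validate", "select",
#'   "revalidate", "downstream")`.
#' @param seed Master seed; stage seeds are derived from it.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param harness A [harness_config()] for the validation stages. The
#'   default is a desk-scale preset (25 iterations, compact grids); pass
#'   `harness_config()` untouched for the full 100-iteration protocol.
#' @param vip_threshold VIP cut for the screening stage.
#' @param top_n Prefix size for the importance intersection.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as JSON via [write_results()] as each stage completes.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "simulate",
                            stages = c("diversity", "cluster", "screen",
                                       "validate", "select", "revalidate",
                                       "downstream"),
                            seed = 1,
                            sim = simulation_config(),
                            harness = NULL,
                            vip_threshold = 1.0,
                            top_n = 30,
                            outdir = NULL) {
  if (is.null(harness)) {
    harness <- harness_config(
      n_iterations = 25, seed = seed,
      grids = list(knn = data.frame(k = c(1, 3, 5, 9, 15)),
                   svm = expand.grid(C = 10^(-1:2), sigma = 10^(-2:0)),
                   bpnn = expand.grid(size = c(2, 8), decay = c(0.01, 0.1)),
                   rf = list(ntree = 500, mtry = c(2, 8, 24)),
                   xgb = expand.grid(nrounds = c(50, 150), max_depth = 3,
                                     eta = 0.1, colsample_bytree = 1,
                                     min_child_weight = 1, subsample = 0.8)))
  }
  sim$seed <- seed
  structure(list(input = input, stages = stages, seed = seed, sim = sim,
                 harness = harness, vip_threshold = vip_threshold,
                 top_n = top_n, outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the fields above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("input", "stages", "seed", "vip_threshold",
                                  "top_n", "outdir"))]
  if (!is.null(y$sim)) args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$harness)) args$harness <- do.call(harness_config, y$harness)
  do.call(pipeline_config, args)
}

#' Run the discovery pipeline
#'
#' Executes the enabled stages in dependency order on simulated or supplied
#' data: diversity profiling, K-means grouping, OPLS-DA screening of key
#' genera (with permutation validation), five-model validation of the key
#' set, characteristic-genus selection by RF/boosting importance
#' intersection, re-validation of the selected set, and the downstream
#' taxa/nutrient/quality analyses (group tests, RDA, network, path model).
#' Fully deterministic under a fixed seed. When `cfg$outdir` is set, each
#' completed stage is persisted before the next starts, so a failing stage
#' leaves the finished ones on disk.
#'
#' @param cfg A [pipeline_config()].
#' @return A [result_bundle()] with one entry per executed stage.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stages <- list()
  persist <- function() {
    if (!is.null(cfg$outdir)) {
      b <- result_bundle(stages, seed = cfg$seed, config = cfg["stages"])
      write_results(b, cfg$outdir)
    }
  }
  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(NULL)
    out <- tryCatch(fn(), error = function(e) {
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages[[name]] <<- out
    persist()
    out
  }

  if (identical(cfg$input, "simulate")) {
    sim <- simulate_dataset(cfg$sim)
    tab <- sim$table; md <- sim$metadata; truth <- sim$truth
  } else {
    tab <- read_abundance_table(cfg$input$table)
    md <- read_sample_metadata(cfg$input$metadata)
    truth <- NULL
  }
  rel <- to_relative_abundance(tab)
  feat <- base::t(rel$values)

  run_stage("diversity", function() {
    alpha <- alpha_diversity_table(tab)
    bc <- bray_curtis_matrix(tab)
    list(alpha = alpha,
         alpha_summary = lapply(alpha[-1], function(v)
           list(min = min(v), mean = mean(v), max = max(v))),
         dominant_taxa = dominant_taxa(tab, 0.01),
         bray_curtis_mean = mean(bc[upper.tri(bc)]))
  })

  groups <- NULL
  run_stage("cluster", function() {
    ga <- kmeans_groups(feat, k = 2, seed = cfg$seed)
    # stable naming: the larger cluster is group A
    sizes <- table(ga$cluster)
    lab <- ifelse(ga$cluster == names(sizes)[which.max(sizes)], "A", "B")
    groups <<- stats::setNames(lab, names(ga$cluster))
    list(k = ga$k, inertia = ga$inertia, sizes = as.list(table(lab)),
         assignment = as.list(groups))
  })
  if (is.null(groups)) {
    if (!"group" %in% names(md)) stop("cluster stage disabled and metadata has no group column")
    groups <- stats::setNames(metadata_field(md, "group"), md$sample_id)
  }
  groups <- groups[colnames(rel$values)]

  model <- NULL; key_taxa <- NULL
  run_stage("screen", function() {
    model <<- fit_oplsda(feat, groups, n_ortho = "auto")
    perm <- permutation_test(feat, groups, n_ortho = model$n_ortho,
                             n_perm = 200, seed = cfg$seed + 1000)
    key_taxa <<- screen_key_taxa(model, cfg$vip_threshold)
    sp <- splot(model, feat)
    list(R2Y = model$R2Y, Q2 = model$Q2, n_ortho = model$n_ortho,
         p_R2Y = perm$p_R2Y, p_Q2 = perm$p_Q2,
         n_key_taxa = length(key_taxa), key_taxa = key_taxa,
         splot_top = utils::head(sp[order(-abs(sp$p1)), ], 20))
  })
  if (is.null(key_taxa)) key_taxa <- taxa_ids(tab)

  run_stage("validate", function() {
    res <- run_ensemble(feat[, key_taxa, drop = FALSE], groups, cfg$harness)
    c(summarize_ensemble(res),
      list(confusion = lapply(res$families, function(f)
        as.list(as.data.frame(f$confusion)))))
  })

  selected <- NULL
  run_stage("select", function() {
    xk <- feat[, key_taxa, drop = FALSE]
    imp_rf <- feature_importance(xk, groups, "rf", seed = cfg$seed + 2000)
    imp_xgb <- feature_importance(xk, groups, "boosting",
                                  seed = cfg$seed + 2000)
    selected <<- top_n_intersection(imp_rf, imp_xgb, n = cfg$top_n)
    out <- list(top_n = cfg$top_n, selected = selected,
                n_selected = length(selected),
                rf_top = imp_rf$ranking[seq_len(cfg$top_n)],
                xgb_top = imp_xgb$ranking[seq_len(cfg$top_n)])
    if (!is.null(truth)) {
      planted <- truth$characteristic_taxa$taxon_id
      out$planted_recall <- length(intersect(selected, planted)) /
        length(planted)
    }
    out
  })
  if (is.null(selected)) selected <- key_taxa

  run_stage("revalidate", function() {
    res <- run_ensemble(feat[, selected, drop = FALSE], groups, cfg$harness)
    summarize_ensemble(res)
  })

  run_stage("downstream", function() {
    nut_vars <- c("available_N", "available_P", "available_K")
    qual_vars <- c("polyphenols", "theanine", "caffeine")
    have <- intersect(c(nut_vars, qual_vars), names(md))
    if (length(have) == 0) return(list(note = "no nutrient/quality metadata"))
    md_ord <- md[match(colnames(rel$values), md$sample_id), ]
    chem <- as.matrix(md_ord[have])
    rownames(chem) <- md_ord$sample_id
    tests <- compare_groups(base::t(chem), groups)
    taxa_m <- feat[, selected, drop = FALSE]
    rda_res <- redundancy_analysis(taxa_m, chem)
    net <- correlation_network(cbind(taxa_m, chem))
    dirn <- compare_groups(base::t(taxa_m), groups)
    pos <- dirn$feature[grepl("^A>", dirn$direction)]
    ordered_ind <- c(intersect(selected, pos), setdiff(selected, pos))
    blocks <- list(bacteria = ordered_ind)
    paths <- list()
    if (all(nut_vars %in% have)) {
      blocks$nutrients <- nut_vars
      paths$nutrients <- "bacteria"
    }
    if (all(qual_vars %in% have) && !is.null(blocks$nutrients)) {
      blocks$quality <- qual_vars
      paths$quality <- "nutrients"
    }
    sem <- if (length(paths) > 0)
      pls_sem(cbind(taxa_m, chem), blocks, paths, n_boot = 500,
              seed = cfg$seed + 3000) else NULL
    list(group_tests = tests,
         rda_proportion_constrained = rda_res$proportion_constrained,
         n_network_edges = nrow(net$edges),
         path_table = if (!is.null(sem)) sem$paths else NULL,
         path_r2 = if (!is.null(sem)) as.list(sem$r_squared) else NULL)
  })

  bundle <- result_bundle(stages, seed = cfg$seed, config = cfg["stages"])
  if (!is.null(cfg$outdir)) write_results(bundle, cfg$outdir)
  bundle
}

#' Render a markdown report from a pipeline bundle
#'
#' Writes a human-readable summary (group sizes, diversity ranges, key- and
#' characteristic-genus counts, per-family AUC/accuracy with cross-family
#' means, group-difference tables, path coefficients) plus the JSON
#' artifacts. Stages absent from the bundle are marked "not run".
#'
#' @param bundle A [result_bundle()] from [run_pipeline()].
#' @param dir Output directory.
#' @return Path of the markdown report, invisibly.
#' @export
render_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(bundle, dir)
  s <- bundle$stages
  ln <- c("# Rhizosphere characteristic-bacteria pipeline report", "")
  add <- function(...) ln <<- c(ln, ...)
  section <- function(name, title, body) {
    add(paste("##", title), "")
    if (is.null(s[[name]])) add("_not run_", "") else body(s[[name]])
  }
  section("cluster", "Sample grouping", function(x) {
    sz <- unlist(x$sizes)
    add(sprintf("K-means split the %d samples into %s.",
                sum(sz), paste(sprintf("group %s (n = %d)", names(sz), sz),
                               collapse = " and ")), "")
  })
  section("diversity", "Diversity", function(x) {
    for (idx in names(x$alpha_summary)) {
      v <- x$alpha_summary[[idx]]
      add(sprintf("- %s: %.3f to %.3f (mean %.3f)", idx, v$min, v$max, v$mean))
    }
    add("", sprintf("%d dominant genera above 1%% mean relative abundance.",
                    length(x$dominant_taxa)), "")
  })
  section("screen", "OPLS-DA screening", function(x) {
    add(sprintf("R2Y = %.3f, Q2 = %.3f (%d orthogonal component(s));",
                x$R2Y, x$Q2, x$n_ortho),
        sprintf("permutation p(R2Y) = %.4g, p(Q2) = %.4g.", x$p_R2Y, x$p_Q2),
        sprintf("%d key genera passed the VIP threshold.", x$n_key_taxa), "")
  })
  fam_table <- function(x) {
    auc <- unlist(x$per_family$auc); acc <- unlist(x$per_family$accuracy_pct)
    add("| family | AUC | overall accuracy (%) |", "|---|---|---|")
    for (f in names(auc))
      add(sprintf("| %s | %.2f | %.2f |", f, auc[[f]], acc[[f]]))
    add(sprintf("| **mean** | **%.2f** | **%.2f** |",
                mean(auc), mean(acc)), "")
  }
  section("validate", "Validation of the key-genus set", fam_table)
  section("select", "Characteristic-genus selection", function(x) {
    add(sprintf("Top-%d intersection of the forest and boosting rankings: %d genera.",
                x$top_n, x$n_selected), "")
  })
  section("revalidate", "Re-validation of the characteristic set", fam_table)
  section("downstream", "Taxa, nutrients and quality", function(x) {
    if (!is.null(x$path_table)) {
      pt <- as.data.frame(x$path_table)
      add("| path | coefficient | bootstrap p |", "|---|---|---|")
      for (i in seq_len(nrow(pt)))
        add(sprintf("| %s -> %s | %.3f | %.3g |",
                    pt$from[i], pt$to[i], pt$estimate[i], pt$p[i]))
      add("")
    }
    add(sprintf("RDA: constrained axes explain %.1f%% of the taxa variance.",
                100 * x$rda_proportion_constrained),
        sprintf("Correlation network retained %d edges.", x$n_network_edges),
        "")
  })
  path <- file.path(dir, "report.md")
  writeLines(ln, path)
  invisible(path)
}
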
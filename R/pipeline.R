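# Pipeline orchestration: synthetic-or-real input through every stage with a
# single master seed and a reproducible report bundle.

#' Build a run configuration
#'
#' Either `synthetic = synthetic_config(...)` or file inputs (`data`, `meta`,
#' `design` paths, optionally `qc_data`); thresholds for every stage; an
#' output directory; one master seed fanning out to per-stage sub-seeds.
#'
#' @param out_dir output directory for the report bundle.
#' @param synthetic optional [synthetic_config()] (takes precedence over file
#'   inputs).
#' @param data,meta,design,qc_data input file paths for real data.
#' @param gmt optional GMT file for enrichment.
#' @param max_missing,max_cv quantifiability thresholds.
#' @param alpha differential significance level.
#' @param r_min,p_corr_max,p_diff_max,endpoint_rule network dual-filter
#'   thresholds.
#' @param classifier list of overrides for [run_classification_stage()].
#' @param run_classifier,run_network stage toggles.
#' @param seed master seed.
#' @export
run_config <- function(out_dir, synthetic = NULL, data = NULL, meta = NULL,
                       design = NULL, qc_data = NULL, gmt = NULL,
                       max_missing = 0.30, max_cv = 0.30, alpha = 0.05,
                       r_min = 0.5, p_corr_max = 0.002, p_diff_max = 0.05,
                       endpoint_rule = "either", classifier = list(),
                       run_classifier = TRUE, run_network = TRUE, seed = 1L) {
  stopifnot(is_fraction(max_missing), is_fraction(max_cv), is_fraction(alpha),
            r_min >= 0, r_min <= 1, is_fraction(p_corr_max), is_fraction(p_diff_max),
            endpoint_rule %in% c("either", "lipid", "both"))
  if (is.null(synthetic) && (is.null(data) || is.null(meta) || is.null(design)))
    stop("either a synthetic config or data+meta+design paths are required")
  structure(list(out_dir = out_dir, synthetic = synthetic, data = data,
                 meta = meta, design = design, qc_data = qc_data, gmt = gmt,
                 max_missing = max_missing, max_cv = max_cv, alpha = alpha,
                 r_min = r_min, p_corr_max = p_corr_max,
                 p_diff_max = p_diff_max, endpoint_rule = endpoint_rule,
                 classifier = classifier, run_classifier = run_classifier,
                 run_network = run_network, seed = as.integer(seed)),
            class = "lpn_run_config")
}

#' Read a YAML run configuration
#' @param path YAML file whose keys mirror [run_config()] arguments; a
#'   `synthetic:` block is passed to [synthetic_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    sc <- y$synthetic
    if (!is.null(sc$group_sizes)) sc$group_sizes <- unlist(sc$group_sizes)
    if (!is.null(sc$n_species_per_class))
      sc$n_species_per_class <- unlist(sc$n_species_per_class)
    y$synthetic <- do.call(synthetic_config, sc)
  }
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full pipeline
#'
#' ingest -> QC filter/impute -> annotate -> differential -> network (+
#' optional enrichment) -> classifier, writing stage outputs plus a manifest
#' (package version, seeds, thresholds, input hashes) under
#' `config$out_dir`. Stage outputs are pure functions of (inputs, config), so
#' a re-run reproduces byte-identical files.
#'
#' @param config a [run_config()].
#' @return Invisible list of stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lpn_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  paths <- character(0)

  # ingest
  if (!is.null(config$synthetic)) {
    lpn_log("ingest", "generating synthetic cohort")
    cohort <- generate_cohort(config$synthetic)
    table <- cohort$table; design <- cohort$design
    qc_tab <- generate_qc_replicates(config$synthetic, n_reps = 10L)
    write_quant_table(table, out("data.csv"), out("meta.csv"))
    write_design(design, out("design.csv"))
    jsonlite::write_json(cohort$truth[c("differential_features",
                                        "correlated_pairs",
                                        "informative_predictors")],
                         out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, out(c("data.csv", "meta.csv", "design.csv", "ground_truth.json")))
  } else {
    for (f in c("data", "meta", "design"))
      if (!file.exists(config[[f]])) stop("ingest: missing ", f, " file: ", config[[f]])
    lpn_log("ingest", "reading ", config$data)
    table <- read_quant_table(config$data, config$meta)
    design <- read_design(config$design)
    qc_tab <- if (!is.null(config$qc_data))
      read_quant_table(config$qc_data, config$meta) else NULL
  }
  check_design_covers(table, design)

  # qc filter + impute
  cv <- if (!is.null(qc_tab)) compute_cv(qc_tab)
        else stats::setNames(rep(0, ncol(table$values)), colnames(table$values))
  flt <- filter_features(table, cv, config$max_missing, config$max_cv)
  table <- impute_half_min(flt$table)
  paths <- c(paths, write_tsv(flt$qc, out("qc_summary.tsv")))

  # annotation
  ann <- annotate_features(table)
  paths <- c(paths, write_tsv(ann, out("annotation.tsv")))
  abund <- subclass_abundance(table)
  paths <- c(paths, write_tsv(abundance_group_summary(abund, design),
                              out("abundance_summary.tsv")))

  # differential
  lpn_log("differential", "testing vs reference ", design_reference(design))
  diff <- differential_analysis(table, design, alpha = config$alpha)
  paths <- c(paths, write_tsv(diff, out("differential.tsv")))
  paths <- c(paths, write_tsv(class_comparison(table, design),
                              out("class_comparison.tsv")))
  z <- group_mean_zscores(class_totals(table), design)
  cl <- hierarchical_cluster(z)
  zdf <- data.frame(feature = rownames(z), z, check.names = FALSE)
  paths <- c(paths, write_tsv(zdf[match(cl$row_order, zdf$feature), ],
                              out("class_zscores.tsv")))
  venn <- venn_sets(diff[diff$layer == "lipid", ], "up")
  paths <- c(paths, write_tsv(
    data.frame(combination = names(venn$counts), count = as.integer(venn$counts)),
    out("venn_up.tsv")))

  # network per non-reference group
  nets <- list()
  if (config$run_network) {
    for (g in setdiff(levels(design$group), design_reference(design))) {
      lpn_log("network", "group ", g)
      edges <- pairwise_correlations(table, design, g)
      net <- dual_filter(edges, diff, config$r_min, config$p_corr_max,
                         config$p_diff_max, config$endpoint_rule, table = table)
      nets[[g]] <- net
      paths <- c(paths,
                 export_network(net, out(sprintf("network_%s.sif", g)), "sif"),
                 export_network(net, out(sprintf("network_%s.tsv", g)), "tsv"),
                 write_tsv(hub_table(net), out(sprintf("hubs_%s.tsv", g))))
    }
    if (!is.null(config$gmt)) {
      sets <- read_gmt(config$gmt)
      universe <- layer_features(table, "protein")
      for (g in names(nets)) {
        hubs <- hub_table(nets[[g]])
        if (!nrow(hubs)) next
        enr <- ora_enrichment(intersect(hubs$protein, universe), sets, universe)
        paths <- c(paths, write_tsv(enr, out(sprintf("enrichment_%s.tsv", g))))
      }
    }
  }

  # classifier
  clf <- NULL
  if (config$run_classifier) {
    clf <- do.call(run_classification_stage,
                   c(list(table = table, design = design,
                          seed = sub_seed(config$seed, "classifier")),
                     config$classifier))
    paths <- c(paths, write_tsv(clf$screening$result, out("predictor_pool.tsv")))
    jsonlite::write_json(
      list(best = clf$search$best, curve = clf$curve,
           traces = lapply(clf$search$traces, `[[`, "steps")),
      out("search_trace.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    paths <- c(paths, out("search_trace.json"))
    for (w in c("train", "test")) {
      ev <- clf[[paste0(w, "_eval")]]
      cm <- as.data.frame.matrix(ev$confusion)
      paths <- c(paths, write_tsv(cbind(truth = rownames(cm), cm),
                                  out(sprintf("confusion_%s.tsv", w))))
    }
  }

  manifest <- list(
    package = "liponet",
    version = as.character(utils::packageVersion("liponet")),
    seed = config$seed,
    thresholds = config[c("max_missing", "max_cv", "alpha", "r_min",
                          "p_corr_max", "p_diff_max", "endpoint_rule")],
    outputs = as.list(tools::md5sum(sort(unique(paths)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  lpn_log("pipeline", "done; manifest at ", out("manifest.json"))
  invisible(list(table = table, design = design, differential = diff,
                 networks = nets, classifier = clf,
                 manifest = manifest, paths = paths))
}
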
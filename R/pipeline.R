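#' Read / write an experiment design as YAML
#'
#' A design document holds `control` (optional arm name) and `populations`,
#' each with `name`, `n_cells`, optional `mean_abundance` (map of component
#' to mean), `cv`, and optional `fold_change` (map).
#'
#' @param design A list as returned by the `preset_*()` functions (elements
#'   `design`, `control`) or a plain list of [population_spec()]s.
#' @param path YAML file path.
#' @return `read_design_yaml`: list with `design` (list of
#'   [population_spec()]) and `control`. `write_design_yaml`: `path`,
#'   invisibly.
#' @export
write_design_yaml <- function(design, path) {
  if (!is.null(design$design)) {
    pops <- design$design
    control <- design$control
  } else {
    pops <- design
    control <- NULL
  }
  doc <- list(
    control = control,
    populations = lapply(pops, function(p) {
      out <- list(name = p$name, n_cells = p$n_cells, cv = p$cv)
      if (!is.null(p$mean_abundance)) {
        out$mean_abundance <- as.list(p$mean_abundance)
      }
      if (!is.null(p$fold_change)) out$fold_change <- as.list(p$fold_change)
      out
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  pops <- lapply(doc$populations, function(p) {
    population_spec(p$name, p$n_cells,
                    mean_abundance = if (!is.null(p$mean_abundance)) {
                      unlist(p$mean_abundance)
                    },
                    cv = p$cv %||% 0.35,
                    fold_change = if (!is.null(p$fold_change)) {
                      unlist(p$fold_change)
                    })
  })
  list(design = pops, control = doc$control)
}

#' Configure an end-to-end profiling run
#'
#' @param panel A [panel_config()] or a panel YAML path (default:
#'   [default_panel()]).
#' @param design A design (preset list, list of [population_spec()]s, or
#'   design YAML path) to simulate from; mutually exclusive with `spectra`.
#' @param spectra A [spectrum_set()] or wide-CSV path of measured spectra.
#' @param labels Optional per-cell metadata data frame (`cell_id`,
#'   `population`) for external spectra.
#' @param qc_threshold Outlier-exclusion Pearson threshold in (0, 1\]
#'   (default 0.95).
#' @param baseline_method `"polynomial"` (default) or `"als"`.
#' @param unmix_mode `"nnls"` or `"ls"`.
#' @param control Control arm label (overrides the design's own).
#' @param noise A [noise_spec()] used when simulating.
#' @param seed Global integer seed.
#' @param out_dir Output directory (created; default `tempfile()`).
#' @param analyses Character subset of `c("embedding", "clusters",
#'   "correlation", "network")`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, design = NULL, spectra = NULL,
                            labels = NULL, qc_threshold = 0.95,
                            baseline_method = "polynomial",
                            unmix_mode = "nnls",
                            control = NULL, noise = noise_spec(), seed = 1,
                            out_dir = tempfile("ramanplex_run_"),
                            analyses = c("embedding", "clusters",
                                         "correlation", "network")) {
  if (!(is.numeric(qc_threshold) && qc_threshold > 0 && qc_threshold <= 1)) {
    stop("qc_threshold must lie in (0, 1]")
  }
  if (!baseline_method %in% c("als", "polynomial")) {
    stop("unknown baseline method '", baseline_method,
         "'; available: als, polynomial")
  }
  if (!unmix_mode %in% c("nnls", "ls")) {
    stop("unmix_mode must be 'nnls' or 'ls'")
  }
  if (is.null(design) && is.null(spectra)) {
    stop("provide either a design to simulate or spectra to analyze")
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(panel)) panel <- read_panel_yaml(panel)
  if (is.null(panel)) panel <- default_panel()
  if (is.character(design)) design <- read_design_yaml(design)
  if (!is.null(design) && is.null(design$design)) {
    design <- list(design = design, control = control)
  }
  if (!is.null(design) && !is.null(control)) design$control <- control
  structure(list(panel = panel, design = design, spectra = spectra,
                 labels = labels, qc_threshold = qc_threshold,
                 baseline_method = baseline_method, unmix_mode = unmix_mode,
                 control = control %||% design$control, noise = noise,
                 seed = as.integer(seed), out_dir = out_dir,
                 analyses = analyses),
            class = "pipeline_config")
}

#' Run the full profiling pipeline
#'
#' Stages: simulate (or load) spectra, remove background, exclude outlier
#' cells (Pearson rule), unmix both windows per cell, assemble the feature
#' table, control-normalize and compute fold changes, then run the
#' requested single-cell analytics (t-SNE embedding, GMM cluster-number
#' selection, correlation matrix, inverse-correlation network). Every
#' artifact is written to `config$out_dir` as CSV/GraphML plus a
#' `provenance.json` (seed, config digest, package version) and a run log;
#' outputs are deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`spectra`,
#'   `truth`, `qc`, `results`, `features`, `normalized`, `fold_changes`,
#'   `embedding`, `clusters`, `correlation`, `network`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("ramanplex %s | seed %d", as.character(utils::packageVersion(
    "ramanplex")), config$seed)
  stage <- "build_library"
  res <- list(out_dir = config$out_dir)
  tryCatch({
    library <- build_library(config$panel, verbose = FALSE)
    logf("library: %d amide + %d silent columns; condition %.4g / %.4g",
         ncol(library$M_amide), ncol(library$M_silent),
         library$condition["amide"], library$condition["silent"])
    logf("component order: %s",
         paste(names(config$panel$components), collapse = ", "))

    stage <- "acquire_spectra"
    if (!is.null(config$design)) {
      sim <- simulate_experiment(config$design$design, config$panel,
                                 config$noise, seed = config$seed,
                                 control = config$design$control,
                                 library = library)
      res$spectra <- sim$spectra
      res$truth <- sim$truth
      write_spectra_csv(sim$spectra,
                        file.path(config$out_dir, "spectra.csv"))
      write_truth_csv(sim$truth, file.path(config$out_dir, "truth.csv"))
      logf("simulated %d cells over %d arms", length(sim$spectra),
           length(config$design$design))
    } else {
      res$spectra <- if (is.character(config$spectra)) {
        read_spectra_csv(config$spectra, meta = config$labels)
      } else config$spectra
      logf("loaded %d cells", length(res$spectra))
    }

    stage <- "background_removal"
    bg <- remove_background(res$spectra, method = config$baseline_method)
    res$corrected <- bg$spectra

    stage <- "qc_filter"
    qc <- filter_outliers(res$corrected, threshold = config$qc_threshold)
    res$qc <- qc$report
    write_qc_report(qc$report,
                    csv_path = file.path(config$out_dir, "qc_report.csv"),
                    json_path = file.path(config$out_dir,
                                          "qc_summary.json"))
    logf("QC: %d/%d cells excluded (r < %.3f): %s", qc$report$n_excluded,
         qc$report$n_input, config$qc_threshold,
         paste(qc$report$excluded_ids, collapse = ", "))

    stage <- "unmix"
    results <- unmix_set(qc$retained, library, mode = config$unmix_mode)
    res$results <- results

    stage <- "feature_table"
    labels <- qc$retained$meta
    res$features <- build_feature_table(results, config$panel,
                                        labels = labels)
    write_feature_csv(res$features,
                      file.path(config$out_dir, "features.csv"))
    logf("feature table: %d cells x %d probe channels",
         nrow(res$features), length(feature_channels(res$features)))

    if (!is.null(config$control) &&
        config$control %in% res$features$population) {
      stage <- "profile"
      nrm <- normalize_to_control(res$features, config$control)
      res$normalized <- nrm
      utils::write.csv(data.frame(population =
                                    rownames(nrm$population_means),
                                  nrm$population_means,
                                  check.names = FALSE),
                       file.path(config$out_dir, "population_means.csv"),
                       row.names = FALSE)
      arms <- setdiff(unique(res$features$population), config$control)
      res$fold_changes <- t(vapply(arms, function(a) {
        fold_change_radar(res$features, a, config$control)
      }, numeric(length(feature_channels(res$features)))))
      utils::write.csv(data.frame(population = arms, res$fold_changes,
                                  check.names = FALSE),
                       file.path(config$out_dir, "fold_changes.csv"),
                       row.names = FALSE)
    }

    ft <- res$features
    if ("embedding" %in% config$analyses && nrow(ft) >= 10) {
      stage <- "embedding"
      res$embedding <- embed_cells(ft, seed = config$seed)
      utils::write.csv(res$embedding,
                       file.path(config$out_dir, "embedding.csv"),
                       row.names = FALSE)
    }
    if ("clusters" %in% config$analyses && nrow(ft) >= 20) {
      stage <- "clusters"
      res$clusters <- select_cluster_number(ft, seed = config$seed)
      utils::write.csv(res$clusters$scores,
                       file.path(config$out_dir, "cluster_scores.csv"),
                       row.names = FALSE)
      logf("selected cluster number k* = %d", res$clusters$k_star)
    }
    if ("correlation" %in% config$analyses && nrow(ft) >= 3) {
      stage <- "correlation"
      res$correlation <- correlation_matrix(ft)
      utils::write.csv(data.frame(channel = rownames(res$correlation$r),
                                  res$correlation$r, check.names = FALSE),
                       file.path(config$out_dir, "correlation.csv"),
                       row.names = FALSE)
    }
    if ("network" %in% config$analyses && !is.null(res$correlation)) {
      stage <- "network"
      res$network <- build_network(res$correlation$r)
      write_network(res$network,
                    csv_path = file.path(config$out_dir, "network_edges.csv"),
                    graphml_path = file.path(config$out_dir,
                                             "network.graphml"))
      utils::write.csv(data.frame(node = names(res$network$centrality),
                                  centrality = res$network$centrality),
                       file.path(config$out_dir, "network_centrality.csv"),
                       row.names = FALSE)
    }

    stage <- "provenance"
    cfg_json <- jsonlite::serializeJSON(config[c("qc_threshold",
                                                 "baseline_method",
                                                 "unmix_mode", "control",
                                                 "seed", "analyses")])
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    digest <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(
      list(package = "ramanplex",
           version = as.character(utils::packageVersion("ramanplex")),
           seed = config$seed, config_md5 = digest,
           qc_threshold = config$qc_threshold,
           baseline_method = config$baseline_method,
           unmix_mode = config$unmix_mode,
           control = config$control, analyses = config$analyses,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      file.path(config$out_dir, "provenance.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs retained in ", config$out_dir, ")",
         call. = FALSE)
  })
  invisible(res)
}
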
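#' Build or read a pipeline configuration
#'
#' Collects the inputs and thresholds of the full analysis. Exactly one input
#' mode must be set: `simulate` (a [simulation_design()] or a list of its
#' arguments), `timeseries_dir` (per-subject TSVs plus parcellation and group
#' CSVs as written by [write_cohort()]), or `connectomes` (a list of
#' precomputed matrices plus a parcellation and group labels). All thresholds
#' default to the canonical analysis values: z > 3 for module assignment,
#' |d| >= 0.5 for effect screens, 5% edge retention, 0.33 consistency,
#' |r| >= 0.5 for behavior, fourfold CV.
#'
#' @param simulate Optional simulation design (or argument list).
#' @param timeseries_dir Optional directory of cohort files.
#' @param connectomes Optional list of connectivity matrices.
#' @param parcellation Parcellation (required with `connectomes`).
#' @param groups Group factor (required with `connectomes`).
#' @param behavior Optional behavior data frame.
#' @param z_threshold,d_threshold,retention_threshold,consistency_threshold,r_threshold
#'   Stage thresholds.
#' @param n_folds CV folds.
#' @param poly_order Detrending order.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, timeseries_dir = NULL,
                            connectomes = NULL, parcellation = NULL,
                            groups = NULL, behavior = NULL,
                            z_threshold = 3, d_threshold = 0.5,
                            retention_threshold = 0.05,
                            consistency_threshold = 0.33,
                            r_threshold = 0.5, n_folds = 4L,
                            poly_order = 2L, seed = 1L, out_dir = NULL) {
  modes <- c(!is.null(simulate), !is.null(timeseries_dir),
             !is.null(connectomes))
  if (sum(modes) != 1L)
    stop("exactly one input mode must be set ",
         "(simulate, timeseries_dir or connectomes)")
  for (th in c(z_threshold, d_threshold, retention_threshold,
               consistency_threshold, r_threshold))
    if (th <= 0) stop("thresholds must be positive")
  structure(list(simulate = simulate, timeseries_dir = timeseries_dir,
                 connectomes = connectomes, parcellation = parcellation,
                 groups = groups, behavior = behavior,
                 z_threshold = z_threshold, d_threshold = d_threshold,
                 retention_threshold = retention_threshold,
                 consistency_threshold = consistency_threshold,
                 r_threshold = r_threshold, n_folds = as.integer(n_folds),
                 poly_order = as.integer(poly_order),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; `.json` is parsed as JSON, anything else as
#'   YAML. Keys mirror the [pipeline_config()] arguments; a `simulate`
#'   mapping is passed to [simulation_design()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!is.null(sim$planted_effects) && is.data.frame(sim$planted_effects))
      sim$planted_effects <- split(sim$planted_effects,
                                   seq_len(nrow(sim$planted_effects)))
    cfg$simulate <- do.call(simulation_design, sim)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full modulewise connectivity analysis
#'
#' Executes every stage in order — input acquisition (simulation or files),
#' connectome construction, block enumeration and SVD summarization,
#' modulewise group comparison, edgewise sign-stratified consistency
#' screening, SVM classification (connectivity features, behavior features
#' when available, and the combined set) and the brain-behavior correlation
#' screen — and optionally writes all stage outputs plus a run manifest.
#' Rerunning with the same configuration and seed is bit-identical.
#'
#' @param config A [pipeline_config()] (or a YAML/JSON path).
#' @return An object of class `"modfc_analysis"` collecting every stage
#'   result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
    invisible(NULL)
  }

  # --- input stage -----------------------------------------------------
  behavior <- config$behavior
  if (!is.null(config$simulate)) {
    design <- config$simulate
    if (!inherits(design, "simulation_design"))
      design <- do.call(simulation_design, design)
    cohort <- generate_group_timeseries(design)
    series <- cohort$series
    parc <- cohort$parcellation
    groups <- cohort$group
    note("input: simulated cohort (", length(series), " subjects, ",
         nrow(parc), " nodes, seed ", design$seed, ")")
  } else if (!is.null(config$timeseries_dir)) {
    d <- config$timeseries_dir
    gf <- file.path(d, "groups.csv")
    if (!file.exists(gf)) stop("missing group file: ", gf)
    gdf <- utils::read.csv(gf, stringsAsFactors = FALSE)
    parc <- read_parcellation_csv(file.path(d, "parcellation.csv"))
    series <- lapply(gdf$subject_id, function(s) {
      f <- file.path(d, paste0(s, "_timeseries.tsv"))
      if (!file.exists(f)) stop("missing time series file: ", f)
      as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                  check.names = FALSE))
    })
    names(series) <- gdf$subject_id
    groups <- factor(gdf$group)
    bf <- file.path(d, "behavior.csv")
    if (is.null(behavior) && file.exists(bf))
      behavior <- utils::read.csv(bf, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    note("input: ", length(series), " subjects read from ", d)
  } else {
    series <- NULL
    parc <- config$parcellation
    groups <- as.factor(config$groups)
    if (is.null(parc) || is.null(groups))
      stop("connectome input mode requires parcellation and groups")
    note("input: ", length(config$connectomes), " precomputed connectomes")
  }

  # --- connectivity ----------------------------------------------------
  connectomes <- if (is.null(series)) {
    lapply(config$connectomes, function(M) {
      M <- as.matrix(M)
      class(M) <- c("connectome", class(M))
      M
    })
  } else {
    build_connectomes(series, poly_order = config$poly_order)
  }
  note("connectivity: ", length(connectomes), " x ",
       nrow(connectomes[[1]]), "-node Pearson matrices")

  # --- modulewise summary ---------------------------------------------
  bi <- enumerate_blocks(parc)
  summaries <- summarize_blocks(connectomes, bi, groups)
  note("blocks: ", nrow(bi$blocks), " blocks, ",
       sum(bi$blocks$n_edges), " edges")

  # --- group comparison ------------------------------------------------
  comparison <- compare_blocks(summaries, d_threshold = config$d_threshold)
  note("modulewise: ", sum(comparison$selected), " blocks with |d| >= ",
       config$d_threshold)

  # --- edgewise consistency -------------------------------------------
  effects <- edgewise_effects(connectomes, groups, bi,
                              d_threshold = config$d_threshold)
  consistency <- lapply(c(positive = "positive", negative = "negative"),
                        function(cls)
    block_consistency(effects, bi, cls,
                      retention_threshold = config$retention_threshold,
                      consistency_threshold = config$consistency_threshold,
                      modulewise = comparison))
  note("edgewise: ",
       sum(vapply(consistency, function(x) sum(x$highly_consistent), 0L)),
       " highly consistent blocks across sign classes")

  # --- MVPA ------------------------------------------------------------
  mvpa <- list(connectivity = fit_classifier_cv(
    summaries$coordinates, groups, n_folds = config$n_folds,
    seed = config$seed, feature_set = "connectivity"))
  behavior_cor <- NULL
  score_correlation <- NULL
  if (!is.null(behavior)) {
    bmat <- as.matrix(behavior[, setdiff(colnames(behavior), "subject_id"),
                               drop = FALSE])
    mvpa$behavior <- fit_classifier_cv(bmat, groups,
                                       n_folds = config$n_folds,
                                       seed = config$seed,
                                       feature_set = "behavior")
    mvpa$combined <- fit_classifier_cv(cbind(summaries$coordinates, bmat),
                                       groups, n_folds = config$n_folds,
                                       seed = config$seed,
                                       feature_set = "combined")
    score_correlation <- correlate_dimensional_scores(
      mvpa$connectivity$dimensional_scores,
      mvpa$behavior$dimensional_scores)
    behavior_cor <- behavior_block_correlations(
      summaries$coordinates, behavior, r_threshold = config$r_threshold)
    note(sprintf("mvpa: connectivity %.1f%%, behavior %.1f%%, combined %.1f%%",
                 100 * mvpa$connectivity$cv_accuracy,
                 100 * mvpa$behavior$cv_accuracy,
                 100 * mvpa$combined$cv_accuracy))
  } else {
    note(sprintf("mvpa: connectivity %.1f%%",
                 100 * mvpa$connectivity$cv_accuracy))
  }

  result <- structure(
    list(config = config, parcellation = parc, groups = groups,
         connectomes = connectomes, block_index = bi,
         summaries = summaries, comparison = comparison,
         edge_effects = effects, consistency = consistency,
         mvpa = mvpa, score_correlation = score_correlation,
         behavior_correlations = behavior_cor, log = log),
    class = "modfc_analysis")

  if (!is.null(config$out_dir)) write_analysis(result, config$out_dir)
  result
}

#' Write all stage outputs of an analysis
#'
#' Writes the coordinate table, block metadata, comparison and consistency
#' CSVs, MVPA JSONs, score scatter data, behavior correlation CSV, the
#' stage log, and a run manifest (seed, thresholds, config hash, package
#' version). Output is deterministic: rerunning an identical configuration
#' reproduces every file byte for byte.
#'
#' @param analysis A `modfc_analysis`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_coordinates_csv(analysis$summaries, file.path(dir, "coordinates.csv"))
  jsonlite::write_json(
    analysis$summaries$block_info,
    file.path(dir, "block_metadata.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(as.data.frame(analysis$comparison),
                   file.path(dir, "modulewise_comparison.csv"),
                   row.names = FALSE)
  write_comparison_csv(analysis$comparison, dir)
  write_consistency_csv(analysis$consistency, dir,
                        edge_effects = analysis$edge_effects)
  for (nm in names(analysis$mvpa))
    write_mvpa_json(analysis$mvpa[[nm]],
                    file.path(dir, paste0("mvpa_", nm, ".json")))
  if (!is.null(analysis$score_correlation)) {
    utils::write.csv(
      data.frame(subject_id = names(analysis$mvpa$connectivity$dimensional_scores),
                 connectivity_score =
                   unname(analysis$mvpa$connectivity$dimensional_scores),
                 behavior_score =
                   unname(analysis$mvpa$behavior$dimensional_scores),
                 group = as.character(analysis$groups)),
      file.path(dir, "dimensional_scores.csv"), row.names = FALSE)
  }
  if (!is.null(analysis$behavior_correlations))
    utils::write.csv(as.data.frame(analysis$behavior_correlations),
                     file.path(dir, "behavior_correlations.csv"),
                     row.names = FALSE)
  writeLines(analysis$log, file.path(dir, "stages.log"))
  cfg <- analysis$config
  manifest <- list(
    package = "modfc",
    version = as.character(utils::packageVersion("modfc")),
    seed = cfg$seed,
    thresholds = list(z = cfg$z_threshold, d = cfg$d_threshold,
                      retention = cfg$retention_threshold,
                      consistency = cfg$consistency_threshold,
                      r = cfg$r_threshold),
    n_folds = cfg$n_folds,
    # hash over analysis parameters only; the output location is not part
    # of the analysis identity
    config_hash = config_hash(utils::capture.output(
      utils::str(cfg[setdiff(names(cfg), "out_dir")]))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.modfc_analysis <- function(x, ...) {
  cat("Modulewise functional connectivity analysis\n")
  cat("  ", paste(x$log, collapse = "\n   "), "\n")
  invisible(x)
}

#' @export
summary.modfc_analysis <- function(object, ...) {
  print(object$comparison)
  for (tab in object$consistency) print(tab)
  for (m in object$mvpa) print(m)
  if (!is.null(object$score_correlation))
    cat(sprintf("score-score correlation: r = %.2f, p = %.4g\n",
                object$score_correlation$r, object$score_correlation$p))
  if (!is.null(object$behavior_correlations))
    print(object$behavior_correlations)
  invisible(object)
}
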
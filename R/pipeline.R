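#' Pipeline configuration
#'
#' Nested configuration for a full run, read from YAML or built in code.
#' Unknown top-level keys are rejected. Every run logs the fully-resolved
#' configuration next to its outputs.
#'
#' @param simulate named list overriding [sim_config()] fields.
#' @param preprocess named list overriding [preprocess_config()] fields.
#' @param features named list overriding [features_config()] fields.
#' @param selection named list: `bins`, `k_grid`.
#' @param classify named list: `n_folds`, `grid` (list of `cost`, `gamma`),
#'   `experiments`, `feature_sets`.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), preprocess = list(),
                            features = list(), selection = list(),
                            classify = list(), seed = 1L) {
  cfg <- list(simulate = simulate, preprocess = preprocess,
              features = features, selection = selection,
              classify = classify, seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("simulate", "preprocess", "features", "selection", "classify", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    dv_stop("dyadvox_config_error", "unknown config keys: %s",
            paste(extra, collapse = ", "))
  check_block <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      dv_stop("dyadvox_config_error", "unknown keys in %s: %s", name,
              paste(bad, collapse = ", "))
  }
  check_block(cfg$simulate, names(formals(sim_config)), "simulate")
  check_block(cfg$preprocess, names(formals(preprocess_config)), "preprocess")
  check_block(cfg$features, names(formals(features_config)), "features")
  check_block(cfg$selection, c("bins", "k_grid"), "selection")
  check_block(cfg$classify, c("n_folds", "grid", "experiments", "feature_sets"),
              "classify")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_key <- function(...) {
  blob <- serialize(list(...), NULL, version = 2)
  # stable content hash via md5 of the serialized payload
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(blob, tmp)
  unname(tools::md5sum(tmp))
}

cached_stage <- function(cache_dir, name, key, compute) {
  path <- file.path(cache_dir, sprintf("%s-%s.rds", name, key))
  if (file.exists(path)) {
    out <- tryCatch(readRDS(path), error = function(e) NULL)
    if (!is.null(out)) {
      dv_log("stage %s: cache hit", name)
      return(list(value = out, path = path, hit = TRUE))
    }
  }
  value <- tryCatch(compute(), error = function(e)
    dv_stop("dyadvox_stage_error", "stage '%s' failed: %s", name,
            conditionMessage(e)))
  saveRDS(value, path)
  list(value = value, path = path, hit = FALSE)
}

#' Run the full pipeline
#'
#' Simulation, feature assembly, classification experiments, and report
#' generation, in order, with each stage's output cached under
#' `out/cache` keyed by a content hash of its configuration, seed and
#' upstream outputs: unchanged reruns skip every stage; a corrupted or
#' stale cache entry is rebuilt, and downstream stages re-run exactly when
#' the content their keys hash actually changed.
#'
#' @param config a `pipeline_config` or path to a YAML file.
#' @param out output directory.
#' @return (invisibly) list with the corpus, feature matrices, experiment
#'   results, and the report table; artifacts under `out`.
#' @export
run_pipeline <- function(config, out) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(out, "cache")
  dir.create(cache, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))

  sim_cfg <- do.call(sim_config, cfg$simulate)
  st_sim <- cached_stage(cache, "simulate", stage_key(sim_cfg, cfg$seed),
                         function() simulate_feature_corpus(sim_cfg, cfg$seed))
  sim <- st_sim$value

  feature_sets <- cfg$classify$feature_sets %||% c("codes", "static")
  key_feat <- stage_key(feature_sets, tools::md5sum(st_sim$path))
  st_feat <- cached_stage(cache, "assemble", key_feat, function() {
    ms <- lapply(feature_sets, function(fs)
      assemble_feature_matrix(sim$corpus, fs))
    names(ms) <- feature_sets
    ms
  })
  mats <- st_feat$value
  for (fs in names(mats))
    write_feature_matrix(mats[[fs]], file.path(out, paste0("features_", fs, ".csv")))

  experiments <- cfg$classify$experiments %||% 1L
  grid <- cfg$classify$grid %||% default_svm_grid()
  n_folds <- cfg$classify$n_folds %||% 10L
  key_exp <- stage_key(experiments, grid, n_folds, cfg$selection,
                       tools::md5sum(st_feat$path))
  st_exp <- cached_stage(cache, "experiments", key_exp, function() {
    res <- list()
    for (fs in names(mats)) {
      res[[fs]] <- list()
      for (e in experiments) {
        res[[fs]][[as.character(e)]] <-
          run_experiment(sim$corpus, fs, e, seed = cfg$seed,
                         features = mats[[fs]], n_folds = n_folds,
                         grid = grid, k_grid = cfg$selection$k_grid,
                         bins = cfg$selection$bins %||% 10L)
      }
    }
    res
  })
  results <- st_exp$value

  report <- results_table(results, sim$corpus)
  utils::write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
  for (fs in names(results))
    for (e in names(results[[fs]])) {
      r <- results[[fs]][[e]]
      utils::write.csv(
        data.frame(sample_id = names(r$predictions), fold = r$fold,
                   truth = r$truth, prediction = r$predictions),
        file.path(out, sprintf("predictions_%s_expt%s.csv", fs, e)),
        row.names = FALSE)
    }
  invisible(list(corpus = sim$corpus, features = mats, results = results,
                 report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
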
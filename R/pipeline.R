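#' Run the screen-to-hits pipeline from a single configuration
#'
#' Wires the pipeline stages — label -> featurize -> train -> screen — from
#' one resolved configuration, writing every stage artefact plus a copy of
#' the resolved config, the seed, the package version and a JSON run log
#' into the output directory. Any prefix of the stage chain can be run by
#' omitting the later stage blocks. A stage failure stops the chain with the
#' failing stage named.
#'
#' The configuration is a named list (or a path to a YAML file) with blocks:
#' \describe{
#'   \item{out_dir}{Artefact directory (required).}
#'   \item{seed}{Global seed (default 1).}
#'   \item{simulate}{Arguments for [screen_sim_config()]; when present a
#'     synthetic screen is generated and used as input.}
#'   \item{screen_csv}{Path to a well-level screen CSV (alternative to
#'     `simulate`).}
#'   \item{label}{Arguments for [label_config()].}
#'   \item{train}{Arguments for [ensemble_config()].}
#'   \item{screen}{Virtual-screen block: `library_csv` (path or data.frame)
#'     and `threshold` (default 0.22), `analogue_distance` (default 0.3).}
#' }
#' Unknown keys are rejected before any computation.
#'
#' @param config Named list or YAML path.
#' @return Invisibly, a list of artefact paths and in-memory stage results
#'   (`labels`, `features`, `ensemble`, `hits`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("out_dir", "seed", "simulate", "screen_csv", "label",
             "train", "screen")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop_glio(paste0("unknown config key(s): ",
                     paste(unknown, collapse = ", ")), "config_error")
  }
  if (is.null(config$out_dir)) stop_glio("out_dir is required", "config_error")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("glioscreen")),
              seed = seed, stages = list())
  resolved <- config
  resolved$seed <- seed
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  results <- list()

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      log$stages[[name]] <<- list(status = "failed",
                                  error = conditionMessage(res))
      jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                           auto_unbox = TRUE, digits = NA)
      stop_glio(sprintf("stage '%s' failed: %s", name,
                        conditionMessage(res)), "pipeline_error")
    }
    log$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  # -- input: simulated or read screen ---------------------------------
  wells <- run_stage("input", function() {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      sim <- generate_screen(do.call(screen_sim_config, sim_args))
      results$truth <<- sim$truth
      sim$wells
    } else if (!is.null(config$screen_csv)) {
      read_screen_table(config$screen_csv)
    } else {
      stop_glio("either 'simulate' or 'screen_csv' must be given",
                "config_error")
    }
  })

  # -- label -----------------------------------------------------------
  labelled <- run_stage("label", function() {
    prof <- normalise_to_dmso(wells)
    dedup <- deduplicate_compounds(prof)
    cfg <- do.call(label_config, config$label %||% list())
    ds <- build_labelled_dataset(dedup$profiles, cfg)
    utils::write.csv(ds$labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    ds
  })
  results$labels <- labelled

  if (is.null(config$train) && is.null(config$screen)) {
    finish_log(log, out_dir)
    return(invisible(c(results, list(out_dir = out_dir))))
  }

  # -- featurize -------------------------------------------------------
  features <- run_stage("featurize", function() {
    lab <- labelled$labels
    can <- canonicalise_smiles(lab$smiles, on_error = "na")
    ok <- !is.na(can)
    raw <- compute_descriptors(stats::setNames(can[ok], lab$compound_id[ok]))
    filt <- drop_constant_features(raw)
    sel <- select_features_by_importance(
      filt, as.integer(lab$label[ok] == "positive"), seed = seed)
    utils::write.csv(data.frame(compound_id = rownames(sel),
                                unclass(sel), check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    list(matrix = sel, labels = as.integer(lab$label[ok] == "positive"))
  })
  results$features <- features

  # -- train -----------------------------------------------------------
  ensemble <- run_stage("train", function() {
    train_args <- config$train %||% list()
    train_args$base_seed <- train_args$base_seed %||% seed
    cfg <- do.call(ensemble_config, train_args)
    ens <- train_ensemble(features$matrix, features$labels, cfg)
    save_ensemble(ens, file.path(out_dir, "ensemble"))
    utils::write.csv(summarise_metrics(ens),
                     file.path(out_dir, "ensemble_metrics.csv"),
                     row.names = FALSE)
    ens
  })
  results$ensemble <- ensemble

  if (is.null(config$screen)) {
    finish_log(log, out_dir)
    return(invisible(c(results, list(out_dir = out_dir))))
  }

  # -- virtual screen --------------------------------------------------
  hits <- run_stage("screen", function() {
    lib <- config$screen$library_csv
    training_can <- canonicalise_smiles(labelled$labels$smiles,
                                        on_error = "na")
    prep <- prepare_screen_library(lib, training_can,
                                   feature_names = ensemble$feature_names)
    preds <- score_library(ensemble, prep$features)
    report <- select_hits(preds, config$screen$threshold %||% 0.22)
    pos_ids <- labelled$labels$compound_id[
      labelled$labels$label == "positive"]
    if (nrow(report$hits) > 0 && length(pos_ids) > 0) {
      pos_can <- training_can[match(pos_ids, labelled$labels$compound_id)]
      pos_feat <- compute_descriptors(
        stats::setNames(pos_can[!is.na(pos_can)],
                        pos_ids[!is.na(pos_can)]))
      shared <- intersect(colnames(pos_feat), ensemble$feature_names)
      scaler <- ensemble$members[[1]]$scaler
      report <- flag_training_analogues(
        report,
        apply_scaler(prep$features[, shared, drop = FALSE],
                     lapply(scaler, function(v) v[shared])),
        apply_scaler(pos_feat[, shared, drop = FALSE],
                     lapply(scaler, function(v) v[shared])),
        config$screen$analogue_distance %||% 0.3)
    }
    utils::write.csv(as.data.frame(preds),
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(report$hits, file.path(out_dir, "hits.csv"),
                     row.names = FALSE)
    report
  })
  results$hits <- hits
  finish_log(log, out_dir)
  invisible(c(results, list(out_dir = out_dir)))
}

finish_log <- function(log, out_dir) {
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
}
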
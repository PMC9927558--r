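## Pipeline orchestration: wires simulate -> featurize -> label -> splits ->
## train -> score -> evaluate with on-disk artifacts, so a whole experiment is
## reproducible from one configuration. Each stage writes documented TSV/JSON
## outputs; a run manifest records the configuration, seeds and the count of
## models excluded for having no contact atoms.

#' Default pipeline configuration
#'
#' A flat key-value list mirrored 1:1 by the command-line flags; every value
#' is serialized into the run manifest of each pipeline run.
#'
#' @param out_dir artifact directory.
#' @param seed master seed for simulation, splits and training.
#' @param ... overrides of any default (unknown keys are an error).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "grank_run", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    n_complexes = 40L, n_decoys = 20L,
    n_res_per_chain = 8L, atoms_per_res = 5L, add_hydrogens = TRUE,
    interface_cutoff = 8.5, edge_cutoff = 4.5, n_rbf = 16L,
    contact_cutoff = 5.0, fnat_cutoff = 0.3,
    node_s = 100L, node_v = 16L, edge_s = 32L, edge_v = 1L,
    n_blocks = 5L, dropout_rate = 0.1, dense_hidden = 128L,
    n_folds = 10L, batch_size = 64L, learning_rate = 1e-4, n_epochs = 50L,
    positive_def = "fnat", magnitude_grid = NULL
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    grank_stop(paste("unknown config keys:", paste(bad, collapse = ", ")),
               "grank_config_error")
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- artifact(cfg, name)
  if (!file.exists(p))
    grank_stop(sprintf(
      "missing artifact '%s': run the '%s' stage first", name, producer),
      "grank_missing_artifact_error")
  p
}

## positives under the configured definition: binary f-nat label (default) or
## CAPRI class at least "acceptable"
positives_under <- function(labels, cfg) {
  if (identical(cfg$positive_def, "capri"))
    labels$capri_class %in% c("high", "medium", "acceptable")
  else
    binary_label(labels$fnat, cfg$fnat_cutoff)
}

#' Run the synthetic benchmark pipeline
#'
#' Executes the requested stages in order against the artifact directory of
#' `config`. Stages: `simulate` (writes decoy PDBs, manifest, natives),
#' `featurize` (interface graphs), `label` (quality labels TSV), `splits`
#' (fold assignment JSON), `train` (fold checkpoints), `score` (ensemble
#' scores TSV), `evaluate` (metrics JSON). `run` is shorthand for all seven.
#'
#' @param config a [run_config()].
#' @param stages character vector, ordered subset of the stage names.
#' @param verbose print stage progress.
#' @return invisibly, the path of the run manifest.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "featurize", "label",
                                    "splits", "train", "score", "evaluate"),
                         verbose = TRUE) {
  all_stages <- c("simulate", "featurize", "label", "splits", "train",
                  "score", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest_path <- artifact(config, "run_manifest.json")
  prev_excluded <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path)$n_excluded_no_contacts %||% 0L else 0L
  runinfo <- list(config = unclass(config), stages = stages,
                  started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  n_excluded_no_contacts = as.integer(prev_excluded))

  if ("simulate" %in% stages) {
    say("simulate: %d complexes x %d decoys", config$n_complexes,
        config$n_decoys)
    recipe <- decoy_recipe(config$n_res_per_chain, config$atoms_per_res,
                           config$add_hydrogens, seed = config$seed)
    ds <- make_dataset(config$n_complexes, config$n_decoys,
                       magnitude_grid = config$magnitude_grid %||%
                         magnitude_grid_default(),
                       seed = config$seed, recipe = recipe,
                       interface_cutoff = config$interface_cutoff,
                       edge_cutoff = config$edge_cutoff,
                       n_rbf = config$n_rbf)
    pdb_dir <- artifact(config, "pdb")
    dir.create(pdb_dir, showWarnings = FALSE)
    rows <- list()
    for (nat in ds$natives)
      write_pdb(nat, file.path(pdb_dir, sprintf("%s_native.pdb",
                                                nat$complex_id)))
    saveRDS(ds, artifact(config, "dataset.rds"))
    for (i in seq_along(ds$decoys)) {
      rel <- file.path("pdb", sprintf("%s_%s.pdb", ds$labels$complex_id[i],
                                      ds$labels$model_id[i]))
      write_pdb(ds$decoys[[i]], file.path(config$out_dir, rel))
      rows[[i]] <- data.frame(
        complex_id = ds$labels$complex_id[i], model_id = ds$labels$model_id[i],
        path = rel, receptor_chain = "A", ligand_chain = "B",
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, artifact(config, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    runinfo$n_excluded_no_contacts <- ds$n_excluded
    say("simulate: %d models kept, %d excluded (no contact atoms)",
        length(ds$graphs), ds$n_excluded)
  }

  if ("featurize" %in% stages) {
    require_artifact(config, "dataset.rds", "simulate")
    ds <- readRDS(artifact(config, "dataset.rds"))
    saveRDS(ds$graphs, artifact(config, "graphs.rds"))
    say("featurize: %d interface graphs", length(ds$graphs))
  }

  if ("label" %in% stages) {
    require_artifact(config, "dataset.rds", "simulate")
    ds <- readRDS(artifact(config, "dataset.rds"))
    utils::write.table(ds$labels, artifact(config, "labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    say("label: wrote %d quality labels", nrow(ds$labels))
  }

  if ("splits" %in% stages) {
    lp <- require_artifact(config, "labels.tsv", "label")
    labels <- utils::read.delim(lp, stringsAsFactors = FALSE)
    splits <- make_splits(unique(labels$complex_id), config$n_folds,
                          seed = config$seed)
    jsonlite::write_json(lapply(splits, unclass),
                         artifact(config, "splits.json"), auto_unbox = TRUE)
    say("splits: %d folds over %d complexes", length(splits),
        length(unique(labels$complex_id)))
  }

  if ("train" %in% stages) {
    require_artifact(config, "graphs.rds", "featurize")
    lp <- require_artifact(config, "labels.tsv", "label")
    sp <- require_artifact(config, "splits.json", "splits")
    graphs <- readRDS(artifact(config, "graphs.rds"))
    labels <- utils::read.delim(lp, stringsAsFactors = FALSE)
    splits <- lapply(jsonlite::read_json(sp, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE),
                     function(s) structure(s, class = "fold_split"))
    mc <- grank_config(node_dims = c(config$node_s, config$node_v),
                       edge_dims = c(config$edge_s, config$edge_v),
                       n_blocks = config$n_blocks,
                       dropout_rate = config$dropout_rate,
                       n_rbf = config$n_rbf,
                       dense_hidden = config$dense_hidden,
                       seed = config$seed)
    tc <- train_config(batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       n_epochs = config$n_epochs, seed = config$seed)
    fit <- grank_fit(graphs, labels, model_config = mc, train_cfg = tc,
                     splits = splits, verbose = verbose)
    ck_dir <- artifact(config, "ckpt")
    dir.create(ck_dir, showWarnings = FALSE)
    for (k in seq_along(fit$states))
      write_grank_state(fit$states[[k]],
                        file.path(ck_dir, sprintf("fold%02d.rds", k)))
    saveRDS(fit, artifact(config, "fit.rds"))
    say("train: %d fold models saved", length(fit$states))
  }

  if ("score" %in% stages) {
    require_artifact(config, "graphs.rds", "featurize")
    require_artifact(config, "fit.rds", "train")
    graphs <- readRDS(artifact(config, "graphs.rds"))
    fit <- readRDS(artifact(config, "fit.rds"))
    preds <- predict(fit, graphs)
    utils::write.table(preds, artifact(config, "scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    say("score: wrote %d ensemble scores", nrow(preds))
  }

  if ("evaluate" %in% stages) {
    sp <- require_artifact(config, "scores.tsv", "score")
    lp <- require_artifact(config, "labels.tsv", "label")
    scores <- utils::read.delim(sp, stringsAsFactors = FALSE)
    labels <- utils::read.delim(lp, stringsAsFactors = FALSE)
    records <- merge(scores, labels, by = c("complex_id", "model_id"))
    records$is_positive <- positives_under(records, config)
    ## restrict assessment to the held-out test complexes when splits exist
    spl_path <- artifact(config, "splits.json")
    if (file.exists(spl_path)) {
      splits <- jsonlite::read_json(spl_path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
      test_ids <- unlist(splits[[1L]]$test)
      records <- records[records$complex_id %in% test_ids, , drop = FALSE]
    }
    metrics <- evaluate_predictions(records)
    sm <- summarize_metrics(metrics)
    sr <- success_rate_table(records)
    jsonlite::write_json(
      list(per_complex = metrics$per_complex,
           summary = sm$summary,
           success_rate = sr,
           n_skipped_no_positives = metrics$n_skipped_no_positives),
      artifact(config, "metrics.json"), dataframe = "rows", digits = NA)
    say("evaluate: metrics over %d test complexes",
        nrow(metrics$per_complex))
  }

  jsonlite::write_json(runinfo, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
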
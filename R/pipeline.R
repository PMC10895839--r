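# Orchestration: a declarative run configuration, per-stage seed fan-out,
# artifact manifests with content hashes, and a stage runner that chains
# synthesize -> prep -> pretrain-align -> pretrain-yield/finetune ->
# evaluate.  Reruns with unchanged config and inputs are skipped unless
# forced.

#' Pipeline run configuration
#'
#' @param out_dir output directory for artifacts and the manifest.
#' @param seed global seed; per-stage seeds are fanned out by stable
#'   hashing of the stage name with the global seed.
#' @param synthetic an `mvrxn_synthetic_spec` describing the dataset.
#' @param split_ratio train/valid/test ratio triple.
#' @param n_bins stratification bins.
#' @param min_frequency vocabulary frequency floor (desk-scale corpora are
#'   small, so the default here is 1; large corpora use 10).
#' @param model_args list of overrides for [build_model()] and the encoder
#'   configs: `embedding_dim`, `hidden_dim`, `num_layers`, `dropout`,
#'   `feature_dim`, `num_interactions`, `num_rbf`, `align_dim`, `max_len`.
#' @param stage1 an `mvrxn_stage1_config`.
#' @param stage2 an `mvrxn_stage2_config`.
#' @return a `mvrxn_run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       synthetic = synthetic_spec(),
                       split_ratio = c(18L, 1L, 1L), n_bins = 10L,
                       min_frequency = 1L,
                       model_args = list(),
                       stage1 = stage1_config(),
                       stage2 = stage2_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, split_ratio = split_ratio,
                 n_bins = n_bins, min_frequency = min_frequency,
                 model_args = model_args, stage1 = stage1, stage2 = stage2),
            class = "mvrxn_run_config")
}

stage_seed <- function(cfg, stage) {
  stable_string_hash(paste(stage, cfg$seed, sep = ":")) %% 2000000000L
}

config_fingerprint <- function(x) {
  # character so the value survives the JSON manifest round trip intact
  as.character(stable_string_hash(paste(deparse(x), collapse = "\n")))
}

artifact_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return("")
  paste(unname(tools::md5sum(paths)), collapse = "+")
}

read_manifest <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (file.exists(mf)) jsonlite::fromJSON(mf, simplifyVector = FALSE)
  else list(stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

PIPELINE_STAGES <- c("make-synthetic", "prep", "pretrain-align", "finetune",
                     "evaluate")

# inputs each stage depends on (artifact files relative to out_dir)
stage_inputs <- function(stage) {
  switch(stage,
         "make-synthetic" = character(0),
         "prep" = "data/reactions.csv",
         "pretrain-align" = c("prep/reactions.csv", "vocab.txt"),
         "finetune" = c("prep/reactions.csv", "vocab.txt", "stage1.rds"),
         "evaluate" = c("prep/reactions.csv", "model.rds"))
}

stage_outputs <- function(stage) {
  switch(stage,
         "make-synthetic" = "data/reactions.csv",
         "prep" = c("prep/reactions.csv", "vocab.txt", "curation_report.json"),
         "pretrain-align" = c("stage1.rds", "stage1_history.csv"),
         "finetune" = c("model.rds", "finetune_history.csv"),
         "evaluate" = c("metrics.json", "predictions.csv"))
}

#' Run pipeline stages
#'
#' Executes the requested stages in order, writing artifacts and a
#' manifest (per-stage config fingerprint, input hashes, outputs) under
#' `cfg$out_dir`.  A stage whose config fingerprint and input hashes match
#' the manifest and whose outputs exist is skipped unless `force = TRUE`;
#' a stage whose dependencies are missing is an error naming the stage.
#'
#' @param cfg a `mvrxn_run_config`.
#' @param stages ordered subset of
#'   `c("make-synthetic", "prep", "pretrain-align", "finetune", "evaluate")`.
#' @param force rerun stages even when up to date.
#' @param verbose print stage progress.
#' @return the manifest (invisibly); each entry lists status and outputs.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES, force = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "mvrxn_run_config"),
            all(stages %in% PIPELINE_STAGES))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(cfg$out_dir)
  od <- function(p) file.path(cfg$out_dir, p)
  for (stage in stages) {
    ins <- od(stage_inputs(stage))
    if (length(ins) && !all(file.exists(ins)))
      stop("orchestration error: stage '", stage, "' is missing inputs: ",
           paste(basename(ins[!file.exists(ins)]), collapse = ", "))
    fp <- config_fingerprint(cfg[c("seed", "synthetic", "split_ratio",
                                   "n_bins", "min_frequency", "model_args",
                                   "stage1", "stage2")])
    in_hash <- artifact_hash(ins)
    prev <- manifest$stages[[stage]]
    up_to_date <- !force && !is.null(prev) &&
      identical(prev$config_fingerprint, fp) &&
      identical(prev$input_hash, in_hash) &&
      all(file.exists(od(stage_outputs(stage))))
    if (up_to_date) {
      manifest$stages[[stage]]$status <- "skipped"
      if (verbose) message("stage ", stage, ": up to date, skipped")
      next
    }
    if (verbose) message("stage ", stage, ": running")
    run_stage(stage, cfg, od)
    manifest$stages[[stage]] <- list(
      status = "completed",
      config_fingerprint = fp,
      input_hash = in_hash,
      outputs = as.list(stage_outputs(stage)),
      output_hash = artifact_hash(od(stage_outputs(stage))))
    write_manifest(manifest, cfg$out_dir)
  }
  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

pipeline_model_cfgs <- function(cfg, vocab) {
  ma <- cfg$model_args
  seq_cfg <- seq_encoder_config(
    vocab_size(vocab),
    embedding_dim = ma$embedding_dim %||% 256L,
    hidden_dim = ma$hidden_dim %||% 128L,
    num_layers = ma$num_layers %||% 2L,
    dropout = ma$dropout %||% 0.3)
  conf_cfg <- schnet_config(
    num_interactions = ma$num_interactions %||% 4L,
    num_rbf = ma$num_rbf %||% 64L,
    feature_dim = ma$feature_dim %||% 128L,
    hidden_dim = ma$hidden_dim %||% 128L,
    num_layers = ma$num_layers %||% 2L,
    dropout = ma$dropout %||% 0.3)
  list(seq = seq_cfg, conf = conf_cfg,
       align_dim = ma$align_dim %||% 128L,
       max_len = ma$max_len %||% 256L)
}

run_stage <- function(stage, cfg, od) {
  if (stage == "make-synthetic") {
    spec <- cfg$synthetic
    spec$seed <- stage_seed(cfg, stage)
    d <- make_synthetic_dataset(spec)
    write_dataset(d, od("data"))
  } else if (stage == "prep") {
    d <- load_dataset(od("data"))
    cur <- curate_dataset(d, embedder = spec_embedder(cfg$synthetic),
                          seed = stage_seed(cfg, stage))
    d <- stratified_split(cur$dataset, ratio = cfg$split_ratio,
                          n_bins = cfg$n_bins,
                          seed = stage_seed(cfg, "split"))
    write_dataset(d, od("prep"))
    write_report(cur$report, od("curation_report.json"))
    corpus <- lapply(d$records, function(r)
      unlist(lapply(reaction_molecules(r),
                    function(m) tokenize_smiles(m$smiles))))
    vocab <- build_vocabulary(corpus, min_frequency = cfg$min_frequency)
    write_vocabulary(vocab, od("vocab.txt"))
  } else if (stage == "pretrain-align") {
    d <- load_dataset(od("prep"))
    vocab <- read_vocabulary(od("vocab.txt"))
    mc <- pipeline_model_cfgs(cfg, vocab)
    model <- build_model(vocab, mc$seq, mc$conf, align_dim = mc$align_dim,
                         max_len = mc$max_len,
                         seed = stage_seed(cfg, "init"))
    s1 <- cfg$stage1
    s1$seed <- stage_seed(cfg, stage)
    fit <- train_stage1(d, model, s1)
    save_checkpoint(fit$model, od("stage1.rds"))
    utils::write.csv(fit$history, od("stage1_history.csv"),
                     row.names = FALSE)
  } else if (stage == "finetune") {
    d <- load_dataset(od("prep"), require_yields = TRUE)
    vocab <- read_vocabulary(od("vocab.txt"))
    model <- load_checkpoint(od("stage1.rds"), vocab = vocab)
    s2 <- cfg$stage2
    s2$seed <- stage_seed(cfg, stage)
    fit <- train_yield_model(d, model, s2)
    save_checkpoint(fit$model, od("model.rds"))
    utils::write.csv(fit$history, od("finetune_history.csv"),
                     row.names = FALSE)
  } else if (stage == "evaluate") {
    d <- load_dataset(od("prep"), require_yields = TRUE)
    model <- load_checkpoint(od("model.rds"))
    test_ids <- split_ids(d, "test")
    pred <- predict_yield(d$records[test_ids], model)
    y <- dataset_yields(d)[test_ids]
    met <- regression_metrics(y, pred$y_pred)
    div <- pair_divergence_distribution(d, model,
                                        seed = stage_seed(cfg, stage),
                                        max_batches = 4L)
    jsonlite::write_json(
      list(mae = met$mae, rmse = met$rmse, r2 = met$r2,
           median_positive_divergence = div$median_positive,
           median_negative_divergence = div$median_negative,
           n_test = length(test_ids)),
      od("metrics.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(
      data.frame(record_id = pred$record_id, y_true = y,
                 y_pred = pred$y_pred),
      od("predictions.csv"), row.names = FALSE)
  } else {
    stop("orchestration error: unknown stage '", stage, "'")
  }
  invisible(NULL)
}
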
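#' Default desk-scale pipeline configuration
#'
#' One list describing the whole experiment: synthetic world, dataset
#' construction, model training, fine-tuning, evaluation and design. The
#' defaults run the full pipeline on a single CPU in minutes using the
#' width-scaled architecture.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    world = list(n_chromosomes = 5L, chromosome_length = 100000L,
                 tissues = c("cns", "epidermis", "gut"), plant_rate = 0.75,
                 noise_sd = 0.2, activity_rule = 2L),
    dataset = list(n_random = 2000L, n_folds = 10L),
    model = list(width_scale = 0.25, replicates = 1L, max_epochs = 40L,
                 patience = 15L, learning_rate = 0.005,
                 convergence_threshold = NULL),
    finetune = list(max_epochs = 30L),
    train = list(tissues = NULL, test_fold = 1L),
    design = list(n_cores = 2000L, target_tissue = NULL,
                  activity_threshold = 0.8, off_target_ceiling = 0.2,
                  n_select = 8L)
  )
}

.validate_config <- function(config) {
  need <- function(path) {
    node <- config
    for (p in path) {
      if (!is.list(node) || is.null(node[[p]]))
        stop("pipeline config is missing field: config$",
             paste(path, collapse = "$"), call. = FALSE)
      node <- node[[p]]
    }
    node
  }
  need(c("world", "tissues"))
  need(c("world", "n_chromosomes"))
  need(c("world", "chromosome_length"))
  need(c("dataset", "n_folds"))
  need(c("model", "width_scale"))
  if (length(config$world$tissues) < 1)
    stop("pipeline config is missing field: config$world$tissues")
  invisible(config)
}

.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp)  # content-stable within a session scope
  unname(tools::md5sum(tmp))
}

# a stage is cached when its stamp matches the hash of the config slice and
# all its output files still exist
.stage_cached <- function(dir, stage, hash, files) {
  stamp <- file.path(dir, paste0(".", stage, ".stamp.json"))
  if (!file.exists(stamp)) return(FALSE)
  info <- tryCatch(jsonlite::read_json(stamp), error = function(e) NULL)
  !is.null(info) && identical(info$hash, hash) &&
    all(file.exists(file.path(dir, files)))
}

.stage_stamp <- function(dir, stage, hash, seconds) {
  jsonlite::write_json(list(hash = hash, seconds = round(seconds, 2),
                            time = format(Sys.time())),
                       file.path(dir, paste0(".", stage, ".stamp.json")),
                       auto_unbox = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate, build-dataset, train-accessibility, fine-tune,
#' evaluate and design in dependency order against a synthetic world,
#' writing artifacts and a run manifest under \code{out_dir}. Stages whose
#' configuration is unchanged and whose outputs exist are skipped, so a
#' re-run with the same config is idempotent.
#'
#' @param config Configuration list (see
#'   \code{\link{default_pipeline_config}}) or the path of a YAML file.
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list (also written as manifest.json).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = 1L, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  # the tissue list is the one field with no sensible default
  if (is.null(config$world) || is.null(config$world$tissues))
    stop("pipeline config is missing field: config$world$tissues",
         call. = FALSE)
  config <- utils::modifyList(default_pipeline_config(), config)
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = seed, config = config, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  tissues <- config$world$tissues
  train_tissues <- config$train$tissues
  if (is.null(train_tissues)) train_tissues <- tissues[1]
  test_fold <- config$train$test_fold

  # -- simulate --------------------------------------------------------------
  whash <- .config_hash(list(config$world, seed))
  wfile <- "world.rds"
  t0 <- tic()
  if (!.stage_cached(out_dir, "simulate", whash, wfile)) {
    say("[simulate] generating synthetic world (seed %d)", seed)
    wc <- do.call(world_config, c(config$world, list(seed = seed)))
    world <- make_world(wc)
    saveRDS(world, file.path(out_dir, wfile))
    world_to_files(world, file.path(out_dir, "world"))
    .stage_stamp(out_dir, "simulate", whash, tic() - t0)
  } else say("[simulate] cached")
  world <- readRDS(file.path(out_dir, wfile))
  manifest$stages$simulate <- list(seconds = round(tic() - t0, 2),
                                   planted_sites = nrow(world$truth))

  # -- build-dataset ---------------------------------------------------------
  dhash <- .config_hash(list(whash, config$dataset))
  t0 <- tic()
  if (!.stage_cached(out_dir, "dataset", dhash, c("dataset.rds", "dataset.tsv"))) {
    say("[build-dataset] tiling and selecting windows")
    ds <- build_regression_dataset(world, n_random = config$dataset$n_random,
                                   n_folds = config$dataset$n_folds,
                                   seed = seed)
    saveRDS(ds, file.path(out_dir, "dataset.rds"))
    write_dataset_table(ds, file.path(out_dir, "dataset.tsv"))
    .stage_stamp(out_dir, "dataset", dhash, tic() - t0)
  } else say("[build-dataset] cached")
  ds <- readRDS(file.path(out_dir, "dataset.rds"))
  manifest$stages$dataset <- list(seconds = round(tic() - t0, 2),
                                  n_examples = nrow(ds$windows))

  # -- train accessibility ---------------------------------------------------
  spec <- architecture_spec(width_scale = config$model$width_scale)
  mhash <- .config_hash(list(dhash, config$model, train_tissues, test_fold))
  t0 <- tic()
  access <- list()
  afiles <- paste0("access_", train_tissues, ".rds")
  if (!.stage_cached(out_dir, "train_access", mhash, afiles)) {
    for (tissue in train_tissues) {
      say("[train-access] %s, fold %d", tissue, test_fold)
      cfg <- train_config(learning_rate = config$model$learning_rate,
                          seed = seed, patience = config$model$patience,
                          max_epochs = config$model$max_epochs)
      ens <- train_fold_ensemble(ds, test_fold, spec, cfg,
                                 replicates = config$model$replicates,
                                 seed = seed,
                                 target_col = match(tissue, colnames(ds$targets)),
                                 threshold = config$model$convergence_threshold)
      access[[tissue]] <- ens
      saveRDS(ens, file.path(out_dir, paste0("access_", tissue, ".rds")))
      save_model(ens$models[[1]],
                 file.path(out_dir, paste0("access_", tissue, "_rep1.rds")))
    }
    .stage_stamp(out_dir, "train_access", mhash, tic() - t0)
  } else {
    say("[train-access] cached")
    for (tissue in train_tissues)
      access[[tissue]] <- readRDS(file.path(out_dir,
                                            paste0("access_", tissue, ".rds")))
  }
  manifest$stages$train_access <- list(seconds = round(tic() - t0, 2),
    test_pcc = lapply(access, function(e)
      vapply(e$models, function(m) m$meta$metric, numeric(1))))

  # -- fine-tune -------------------------------------------------------------
  fhash <- .config_hash(list(mhash, config$finetune))
  t0 <- tic()
  labels <- label_records(world$activity, world_term_map(world))
  activity <- list()
  clf <- list()
  ffiles <- paste0("activity_", train_tissues, ".rds")
  if (!.stage_cached(out_dir, "finetune", fhash, ffiles)) {
    for (tissue in train_tissues) {
      say("[finetune] %s", tissue)
      act_ds <- build_activity_dataset(labels, tissue, world$genome,
                                       world$peaks[[tissue]], ds$fold_plan,
                                       seed = seed)
      cfg <- train_config(learning_rate = 1e-4, loss = "bce", patience = 20L,
                          max_epochs = config$finetune$max_epochs,
                          seed = seed)
      model <- fine_tune(access[[tissue]]$models[[1]], act_ds, test_fold,
                         cfg, seed = seed)
      clf[[tissue]] <- model
      activity[[tissue]] <- act_ds
      saveRDS(model, file.path(out_dir, paste0("activity_", tissue, ".rds")))
    }
    .stage_stamp(out_dir, "finetune", fhash, tic() - t0)
  } else {
    say("[finetune] cached")
    for (tissue in train_tissues) {
      clf[[tissue]] <- readRDS(file.path(out_dir,
                                         paste0("activity_", tissue, ".rds")))
      activity[[tissue]] <- build_activity_dataset(labels, tissue,
                                                   world$genome,
                                                   world$peaks[[tissue]],
                                                   ds$fold_plan, seed = seed)
    }
  }
  manifest$stages$finetune <- list(seconds = round(tic() - t0, 2),
    test_auc = lapply(clf, function(m) m$meta$metric))

  # -- evaluate --------------------------------------------------------------
  t0 <- tic()
  eval_metrics <- list()
  for (tissue in train_tissues) {
    act_ds <- activity[[tissue]]
    split <- dataset_split(act_ds, test_fold)
    pred <- predict(clf[[tissue]], act_ds$seq[split$test])
    y <- act_ds$targets[split$test, 1]
    eval_metrics[[tissue]] <- classification_metrics(pred, y)
    utils::write.table(ppv_curve(pred, y),
                       file.path(out_dir, paste0("ppv_", tissue, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(eval_metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$stages$evaluate <- list(seconds = round(tic() - t0, 2),
                                   metrics = eval_metrics)

  # -- design ----------------------------------------------------------------
  t0 <- tic()
  target <- config$design$target_tissue
  if (is.null(target)) target <- train_tissues[1]
  say("[design] screening %d random cores for %s",
      config$design$n_cores, target)
  cores <- generate_random_cores(config$design$n_cores, seed = seed)
  policy <- selection_policy(
    activity_threshold = config$design$activity_threshold,
    off_target_ceiling = config$design$off_target_ceiling,
    max_candidates = config$design$n_select, seed = seed)
  candidates <- screen_candidates(cores, clf[target],
                                  access[[target]], target, policy)
  utils::write.table(as.data.frame(candidates),
                     file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(candidates)) {
    fa <- stats::setNames(candidates$core,
                          sprintf("%s_synth%d", target, candidates$rank))
    write_fasta(fa, file.path(out_dir, "candidates.fa"))
  }
  manifest$stages$design <- list(seconds = round(tic() - t0, 2),
    n_screened = length(cores), n_selected = nrow(candidates))

  manifest$config_hash <- .config_hash(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
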
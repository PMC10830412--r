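#' Parse stage annotation terms like "stage13-16"
#'
#' @param stage_term Character vector ("stageA-B" or "stageA").
#' @return Two-column matrix (from, to); NA rows for unparseable terms.
#' @export
parse_stage_term <- function(stage_term) {
  m <- regmatches(stage_term,
                  regexec("^stage([0-9]+)(?:-([0-9]+))?$", stage_term))
  t(vapply(m, function(g) {
    if (length(g) == 0) return(c(NA_integer_, NA_integer_))
    from <- as.integer(g[2])
    to <- if (nzchar(g[3])) as.integer(g[3]) else from
    c(from, to)
  }, integer(2)))
}

#' Derive per-tissue activity labels from annotation records
#'
#' A tile is active for a tissue when some record for it carries an active
#' annotation whose stage range overlaps the target stages (13-16 by
#' default) and whose term is in the tissue's term list. Tissues may
#' additionally carry exclusion terms (e.g. brain-specific activity
#' requires no activity in ventral-nerve-cord terms): a tile with an active
#' matching exclusion record is labeled inactive for that tissue. All other
#' tiles are inactive. Terms matching no tissue raise a warning and are
#' ignored.
#'
#' @param records data.frame with columns chrom, start, end, stage_term,
#'   tissue_term, label ("active"/"inactive").
#' @param term_map Named list per tissue: \code{list(terms = ...,
#'   exclude_terms = ...)} (exclude_terms optional).
#' @param stages Length-2 integer vector of target stages (inclusive).
#' @return data.frame with one row per unique tile (chrom, start, end) and
#'   one logical column per tissue.
#' @export
label_records <- function(records, term_map, stages = c(13L, 16L)) {
  required <- c("chrom", "start", "end", "stage_term", "tissue_term", "label")
  if (!all(required %in% names(records)))
    stop("records must have columns: ", paste(required, collapse = ", "))
  known <- unique(unlist(lapply(term_map, function(x)
    c(x$terms, x$exclude_terms))))
  unknown <- setdiff(unique(records$tissue_term), known)
  if (length(unknown))
    warning("ignoring unknown annotation term(s): ",
            paste(unknown, collapse = ", "))
  sr <- parse_stage_term(records$stage_term)
  in_stage <- !is.na(sr[, 1]) & sr[, 1] <= stages[2] & sr[, 2] >= stages[1]
  active_rec <- records$label == "active" & in_stage

  key <- paste(records$chrom, records$start, records$end, sep = ":")
  tiles <- records[!duplicated(key), c("chrom", "start", "end")]
  tile_key <- paste(tiles$chrom, tiles$start, tiles$end, sep = ":")
  for (tissue in names(term_map)) {
    hit <- active_rec & records$tissue_term %in% term_map[[tissue]]$terms
    act <- tile_key %in% key[hit]
    excl <- term_map[[tissue]]$exclude_terms
    if (length(excl)) {
      bad <- active_rec & records$tissue_term %in% excl
      act <- act & !(tile_key %in% key[bad])
    }
    tiles[[tissue]] <- act
  }
  rownames(tiles) <- NULL
  tiles
}

#' Build the in-vivo activity classification dataset for one tissue
#'
#' Labeled fragments are tiled into 1,001-bp windows; positives are tiles
#' from active fragments that overlap an accessibility peak of the tissue
#' by at least 151 bp, negatives are tiles from inactive fragments
#' down-sampled (seeded) to at most five tiles per source fragment.
#' Reverse-complement augmentation doubles the set; folds are inherited
#' from the accessibility-stage chromosome-half plan so test sets are fully
#' held out across both training stages.
#'
#' @param labels Output of \code{\link{label_records}} (tile coordinates
#'   plus one logical column per tissue).
#' @param tissue Target tissue (a column of \code{labels}).
#' @param genome Genome assembly.
#' @param peaks GRanges of the tissue's accessibility peaks.
#' @param plan The accessibility \code{fold_plan}.
#' @param seed Seed for negative down-sampling.
#' @param tile_stride Stride for tiling fragments (bp).
#' @param window_len Tile length (default 1001).
#' @param min_peak_overlap Minimum tile/peak overlap for positives (bp).
#' @param max_neg_per_fragment Negative tiles kept per fragment.
#' @return An \code{activity_dataset} (augmented, folds assigned): windows,
#'   sequences, a one-column \code{targets} matrix of 0/1 labels, folds.
#' @export
build_activity_dataset <- function(labels, tissue, genome, peaks, plan,
                                   seed = 1L, tile_stride = 500L,
                                   window_len = 1001L,
                                   min_peak_overlap = 151L,
                                   max_neg_per_fragment = 5L) {
  if (!tissue %in% names(labels)) stop("no label column for tissue ", tissue)
  tile_rows <- list()
  for (i in seq_len(nrow(labels))) {
    fs <- labels$start[i]; fe <- labels$end[i]
    if (fe - fs + 1L < window_len) next
    starts <- seq(fs, fe - window_len + 1L, by = tile_stride)
    tile_rows[[i]] <- data.frame(
      chrom = labels$chrom[i], start = starts, end = starts + window_len - 1L,
      fragment = i, active = labels[[tissue]][i], stringsAsFactors = FALSE)
  }
  tiles <- do.call(rbind, tile_rows)
  if (is.null(tiles) || !nrow(tiles)) stop("no fragments long enough to tile")
  gr <- GenomicRanges::GRanges(tiles$chrom,
                               IRanges::IRanges(tiles$start, tiles$end))
  ov <- GenomicRanges::countOverlaps(gr, peaks,
                                     minoverlap = min_peak_overlap) > 0
  pos <- tiles[tiles$active & ov, , drop = FALSE]
  if (!nrow(pos)) stop("zero positive tiles for tissue ", tissue)
  neg <- tiles[!tiles$active, , drop = FALSE]
  local_seed(seed)
  keep_neg <- unlist(lapply(split(seq_len(nrow(neg)), neg$fragment),
    function(ix) if (length(ix) <= max_neg_per_fragment) ix
                 else sort(sample(ix, max_neg_per_fragment))),
    use.names = FALSE)
  neg <- neg[sort(keep_neg), , drop = FALSE]
  all_tiles <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  gr <- GenomicRanges::GRanges(all_tiles$chrom,
                               IRanges::IRanges(all_tiles$start, all_tiles$end))
  ds <- new_regression_dataset(
    windows = data.frame(chrom = all_tiles$chrom, start = all_tiles$start,
                         end = all_tiles$end, strand = "+",
                         origin = ifelse(y == 1, "positive", "negative"),
                         source_id = seq_along(y), stringsAsFactors = FALSE),
    seq = interval_sequences(genome, gr),
    targets = matrix(y, ncol = 1, dimnames = list(NULL, "label")))
  ds$fold <- fold_of_intervals(plan, ds$windows$chrom, ds$windows$start,
                               ds$windows$end)
  ds$fold_plan <- plan
  ds <- augment_reverse_complement(ds)
  class(ds) <- c("activity_dataset", class(ds))
  ds
}

#' @export
print.activity_dataset <- function(x, ...) {
  y <- x$targets[, 1]
  cat(sprintf("Activity dataset: %d examples%s (%d positive, %d negative)\n",
              length(y),
              if (x$augmented) " (reverse-complement augmented)" else "",
              sum(y == 1), sum(y == 0)))
  invisible(x)
}

#' Initialize an activity classifier from an accessibility model
#'
#' Transfer learning: all convolutional and dense weights (including batch
#' normalization statistics) are copied from the trained accessibility
#' regression model and kept trainable; the final layer is replaced by a
#' freshly initialized sigmoid unit.
#'
#' @param source A trained regression \code{cnn_model}.
#' @param seed Seed for the new head's initialization.
#' @return An untrained classification \code{cnn_model}.
#' @export
transfer_init <- function(source, seed = 1L) {
  stopifnot(inherits(source, "cnn_model"))
  if (source$spec$head != "linear")
    stop("transfer source must be a regression (linear-head) model")
  if (!isTRUE(source$meta$trained))
    stop("transfer source must be trained")
  spec <- source$spec
  spec$head <- "sigmoid"
  target <- build_model(spec, seed = seed)
  target$params$conv <- source$params$conv
  target$params$dense <- source$params$dense
  target$meta$init <- "transfer"
  target$meta$source_task <- "accessibility"
  target
}

# rank-based ROC AUC (Mann-Whitney; ties get midranks)
.auc_roc <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Train a model on one cross-validation rotation of a dataset
#'
#' Trains on the eight training folds, early-stops on the validation fold
#' and evaluates on the held-out test fold (non-augmented windows only).
#' The held-out metric (Pearson correlation for regression, ROC AUC for
#' classification) is stored in \code{meta$metric} for the convergence
#' filter.
#'
#' @param model An untrained \code{cnn_model}.
#' @param dataset \code{regression_dataset} or \code{activity_dataset} with
#'   folds assigned.
#' @param test_fold Held-out fold id.
#' @param config \code{\link{train_config}}.
#' @param target_col Which target column to fit (default 1).
#' @return The trained model with \code{meta$metric} and
#'   \code{meta$test_fold} set.
#' @export
train_on_fold <- function(model, dataset, test_fold, config = train_config(),
                          target_col = 1L) {
  split <- dataset_split(dataset, test_fold)
  y <- dataset$targets[, target_col]
  model <- train_cnn(model,
                     dataset$seq[split$train], y[split$train],
                     dataset$seq[split$val], y[split$val],
                     config = config)
  pred <- predict(model, dataset$seq[split$test])
  model$meta$metric <- if (model$spec$head == "linear")
    pearson(pred, y[split$test]) else .auc_roc(pred, y[split$test])
  model$meta$test_fold <- test_fold
  model
}

#' Train a replicate ensemble on one held-out fold
#'
#' Trains \code{replicates} models with different seeds, applies the
#' convergence filter (test PCC > 0.1 for regression, test AUC > 0.7 for
#' classification) and bundles the converged replicates into an ensemble
#' whose prediction is their mean.
#'
#' @param dataset Dataset with folds assigned.
#' @param test_fold Held-out fold id.
#' @param spec \code{\link{architecture_spec}}; its head selects the task.
#' @param config \code{\link{train_config}}.
#' @param replicates Number of replicate models (default 3).
#' @param seed Base seed; replicate r uses seed + r - 1.
#' @param init Either "fresh" (random initialization) or a trained
#'   regression model to transfer from.
#' @param target_col Target column.
#' @param threshold Convergence cutoff passed to
#'   \code{\link{convergence_filter}} (NULL for the task default).
#' @return A \code{cnn_ensemble} of converged replicates.
#' @export
train_fold_ensemble <- function(dataset, test_fold, spec,
                                config = train_config(), replicates = 3L,
                                seed = 1L, init = "fresh", target_col = 1L,
                                threshold = NULL) {
  task <- if (spec$head == "linear") "regression" else "classification"
  models <- lapply(seq_len(replicates), function(r) {
    rseed <- seed + r - 1L
    m <- if (inherits(init, "cnn_model")) transfer_init(init, seed = rseed)
         else build_model(spec, seed = rseed)
    cfg <- config
    cfg$seed <- rseed
    train_on_fold(m, dataset, test_fold, cfg, target_col)
  })
  cnn_ensemble(convergence_filter(models, task, threshold))
}

#' Fine-tune an accessibility model into an activity classifier
#'
#' Stage-two defaults: Adam with learning rate 1e-4, binary cross-entropy,
#' batch size 128 and early stopping with patience of twenty epochs.
#'
#' @param source Trained accessibility \code{cnn_model} (or an already
#'   initialized sigmoid-head model).
#' @param dataset \code{activity_dataset}.
#' @param test_fold Held-out fold id.
#' @param config Training configuration; defaults to the stage-two recipe.
#' @param seed Seed for head initialization and training.
#' @return Trained classifier with held-out AUC in \code{meta$metric}.
#' @export
fine_tune <- function(source, dataset, test_fold,
                      config = train_config(learning_rate = 1e-4,
                                            loss = "bce", patience = 20L),
                      seed = 1L) {
  model <- if (source$spec$head == "sigmoid") source
           else transfer_init(source, seed = seed)
  config$seed <- as.integer(seed)
  train_on_fold(model, dataset, test_fold, config)
}

#' Baseline activity classifiers isolating the transfer effect
#'
#' Same architecture, data and training regime as \code{\link{fine_tune}};
#' only the initialization differs. \code{"random_init"} starts from fresh
#' random weights; \code{"off_tissue"} initializes from an accessibility
#' model of a non-target tissue (with several donors, the donor with the
#' best validation-fold AUPRC is kept; ties break lexicographically by
#' donor name).
#'
#' @param mode "random_init" or "off_tissue".
#' @param dataset \code{activity_dataset}.
#' @param test_fold Held-out fold id.
#' @param donors Named list of donor accessibility models (off_tissue).
#' @param config Training configuration (stage-two defaults).
#' @param seed Seed.
#' @param spec Architecture for the random initialization (must match the
#'   transfer model's architecture for a fair comparison); defaults to the
#'   full-width classifier for the dataset's window length.
#' @return Trained classifier; for off_tissue, \code{meta$donor} records the
#'   selected donor.
#' @export
baseline_train <- function(mode = c("random_init", "off_tissue"), dataset,
                           test_fold, donors = NULL,
                           config = train_config(learning_rate = 1e-4,
                                                 loss = "bce",
                                                 patience = 20L),
                           seed = 1L, spec = NULL) {
  mode <- match.arg(mode)
  config$seed <- as.integer(seed)
  if (mode == "random_init") {
    if (is.null(spec)) spec <- dataset_arch_spec(dataset)
    if (spec$head != "sigmoid") { spec$head <- "sigmoid" }
    model <- build_model(spec, seed = seed)
    return(train_on_fold(model, dataset, test_fold, config))
  }
  if (is.null(donors) || !length(donors))
    stop("off_tissue baseline requires at least one donor model")
  if (inherits(donors, "cnn_model")) donors <- list(donor = donors)
  donors <- donors[order(names(donors))]
  fitted <- lapply(names(donors), function(nm)
    fine_tune(donors[[nm]], dataset, test_fold, config, seed = seed))
  if (length(fitted) == 1) {
    fitted[[1]]$meta$donor <- names(donors)[1]
    return(fitted[[1]])
  }
  split <- dataset_split(dataset, test_fold, originals_only_test = FALSE)
  val_auprc <- vapply(fitted, function(m)
    auprc(predict(m, dataset$seq[split$val]),
          dataset$targets[split$val, 1]), numeric(1))
  best <- which.max(val_auprc)  # which.max keeps the first (lexicographic) tie
  out <- fitted[[best]]
  out$meta$donor <- names(donors)[best]
  out
}

# default classification architecture matching a dataset's window length
dataset_arch_spec <- function(dataset, width_scale = 1) {
  architecture_spec(input_length = nchar(dataset$seq[1]), head = "sigmoid",
                    width_scale = width_scale)
}

#' Compare transfer learning against baseline initializations
#'
#' Trains matched classifiers (transfer, random initialization and, when
#' donors are given, off-tissue pre-training) across seeds and reports the
#' held-out AUPRC of each, evaluated on the non-augmented test-fold
#' examples.
#'
#' @param dataset \code{activity_dataset}.
#' @param test_fold Held-out fold id.
#' @param source Trained accessibility model of the target tissue.
#' @param donors Optional named list of off-tissue donor models.
#' @param seeds Integer vector of seeds.
#' @param config Training configuration (stage-two defaults).
#' @return data.frame (mode, seed, auprc, auc).
#' @export
compare_initializations <- function(dataset, test_fold, source,
                                    donors = NULL, seeds = 1:3,
                                    config = train_config(
                                      learning_rate = 1e-4, loss = "bce",
                                      patience = 20L)) {
  split <- dataset_split(dataset, test_fold)
  y <- dataset$targets[split$test, 1]
  match_spec <- source$spec
  match_spec$head <- "sigmoid"
  rows <- list()
  for (seed in seeds) {
    models <- list(
      transfer = fine_tune(source, dataset, test_fold, config, seed = seed),
      random_init = baseline_train("random_init", dataset, test_fold,
                                   config = config, seed = seed,
                                   spec = match_spec))
    if (!is.null(donors))
      models$off_tissue <- baseline_train("off_tissue", dataset, test_fold,
                                          donors = donors, config = config,
                                          seed = seed)
    for (mode in names(models)) {
      pred <- predict(models[[mode]], dataset$seq[split$test])
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, seed = seed, auprc = auprc(pred, y),
        auc = .auc_roc(pred, y), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
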
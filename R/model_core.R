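#' Architecture specification for sequence models
#'
#' Describes the convolutional network shared by the sequence-to-accessibility
#' (regression) and sequence-to-activity (classification) models: four 1D
#' convolution layers (filters 256, 120, 60, 60; widths 7, 3, 3, 3; same
#' padding), each followed by batch normalization, ReLU and max-pooling of
#' size 3, then two dense layers (64 and 256 units) with batch normalization,
#' ReLU and dropout 0.4, and a single-unit head (linear for regression,
#' sigmoid for classification).
#'
#' @param input_length Sequence length the model consumes (default 1001).
#' @param conv_filters Integer vector of filters per convolution layer.
#' @param conv_widths Integer vector of kernel widths, same length.
#' @param dense_units Integer vector of dense layer sizes.
#' @param dropout Dropout fraction on dense activations, in [0, 1).
#' @param head "linear" or "sigmoid".
#' @param width_scale Multiplier applied to the convolution filter counts for
#'   reduced-width runs (rounded, minimum 1; the dense layers are cheap and
#'   keep their size). 1 reproduces the full model.
#' @return An object of class \code{architecture_spec}.
#' @export
architecture_spec <- function(input_length = 1001L,
                              conv_filters = c(256L, 120L, 60L, 60L),
                              conv_widths = c(7L, 3L, 3L, 3L),
                              dense_units = c(64L, 256L),
                              dropout = 0.4,
                              head = c("linear", "sigmoid"),
                              width_scale = 1) {
  head <- match.arg(head)
  if (length(conv_filters) != length(conv_widths))
    stop("conv_filters and conv_widths must have equal length")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (width_scale <= 0) stop("width_scale must be positive")
  if (any(conv_widths %% 2 == 0)) stop("conv widths must be odd (same padding)")
  conv_filters <- pmax(1L, as.integer(round(conv_filters * width_scale)))
  pool <- 3L
  min_len <- pool^length(conv_filters)
  if (input_length < min_len)
    stop(sprintf("input_length %d too short for %d max-pool(%d) stages; minimum is %d",
                 input_length, length(conv_filters), pool, min_len))
  structure(list(
    input_length = as.integer(input_length),
    conv_filters = conv_filters,
    conv_widths = as.integer(conv_widths),
    dense_units = dense_units,
    dropout = dropout,
    head = head,
    pool = pool
  ), class = "architecture_spec")
}

#' Training configuration
#'
#' Defaults follow the accessibility-regression stage: Adam with learning
#' rate 0.005, mean-squared-error loss, batch size 128 and early stopping
#' with patience of five epochs. The fine-tuning stage uses
#' \code{learning_rate = 1e-4}, \code{loss = "bce"} and \code{patience = 20}
#' (see \code{\link{fine_tune}}).
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param loss "mse" or "bce".
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param max_epochs Upper bound on epochs.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.005, loss = c("mse", "bce"),
                         batch_size = 128L, patience = 5L,
                         max_epochs = 100L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, patience >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, loss = loss,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# flattened length after the pooling stages
.flat_dim <- function(spec) {
  L <- spec$input_length
  for (i in seq_along(spec$conv_filters)) L <- L %/% spec$pool
  L * spec$conv_filters[length(spec$conv_filters)]
}

.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained sequence model
#'
#' Initializes the network weights (Glorot-uniform, seeded) for the given
#' architecture. The result is a \code{cnn_model} that can be trained with
#' \code{\link{train_cnn}} or used directly with \code{predict}.
#'
#' @param spec An \code{\link{architecture_spec}}.
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{cnn_model}.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  local_seed(seed)
  nconv <- length(spec$conv_filters)
  conv <- vector("list", nconv)
  cin <- 4L
  for (i in seq_len(nconv)) {
    f <- spec$conv_filters[i]; k <- spec$conv_widths[i]
    conv[[i]] <- list(
      W = .glorot(f, cin * k, fan_in = cin * k, fan_out = f * k),
      b = numeric(f), gamma = rep(1, f), beta = numeric(f),
      rmean = numeric(f), rvar = rep(1, f))
    cin <- f
  }
  dense <- vector("list", length(spec$dense_units))
  din <- .flat_dim(spec)
  for (i in seq_along(spec$dense_units)) {
    u <- spec$dense_units[i]
    dense[[i]] <- list(
      W = .glorot(u, din, fan_in = din, fan_out = u),
      b = numeric(u), gamma = rep(1, u), beta = numeric(u),
      rmean = numeric(u), rvar = rep(1, u))
    din <- u
  }
  head <- list(W = .glorot(1, din, fan_in = din, fan_out = 1), b = numeric(1))
  structure(list(
    spec = spec,
    params = list(conv = conv, dense = dense, head = head),
    history = NULL,
    meta = list(task = if (spec$head == "sigmoid") "classification" else "regression",
                init_seed = seed, trained = FALSE, converged = NA,
                metric = NA_real_)
  ), class = "cnn_model")
}

#' Number of trainable parameters of a model
#'
#' Counts convolution and dense weights/biases plus batch-norm scale and
#' shift (running statistics are not trainable).
#'
#' @param model A \code{cnn_model}.
#' @return Integer count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  p <- model$params
  n <- 0L
  for (ly in p$conv) n <- n + length(ly$W) + length(ly$b) +
    length(ly$gamma) + length(ly$beta)
  for (ly in p$dense) n <- n + length(ly$W) + length(ly$b) +
    length(ly$gamma) + length(ly$beta)
  n + length(p$head$W) + length(p$head$b)
}

.arch_for_cpp <- function(model) {
  s <- model$spec
  list(input_length = s$input_length, conv_widths = s$conv_widths,
       head = s$head, dropout = s$dropout)
}

# sequences (character vector) -> integer code matrix L x n
seqs_to_codes <- function(seqs, input_length) {
  lens <- nchar(seqs)
  if (any(lens != input_length))
    stop(sprintf("sequence length(s) %s do not match model input length %d",
                 paste(unique(lens[lens != input_length]), collapse = ","),
                 input_length))
  codes <- vapply(seqs, dna_codes, integer(input_length), USE.NAMES = FALSE)
  matrix(codes, nrow = input_length)
}

#' Train a sequence model
#'
#' Runs minibatch Adam with early stopping: training stops when the
#' validation loss fails to improve for \code{patience} consecutive epochs
#' (or at \code{max_epochs}) and the best-validation weights are restored.
#' The run is fully seeded and reproducible.
#'
#' @param model A \code{cnn_model} from \code{\link{build_model}}.
#' @param x Training sequences (character vector) or an integer code matrix.
#' @param y Numeric targets (regression) or 0/1 labels (classification).
#' @param val_x,val_y Validation data, disjoint from training.
#' @param config A \code{\link{train_config}}.
#' @return The trained \code{cnn_model} with a \code{history} data frame of
#'   per-epoch training and validation loss.
#' @export
train_cnn <- function(model, x, y, val_x, val_y, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (length(y) == 0) stop("empty training set")
  if (model$spec$head == "sigmoid") {
    if (config$loss != "bce") stop("sigmoid head requires loss = 'bce'")
    if (length(unique(y)) < 2) stop("degenerate classes: training labels are constant")
  } else if (config$loss != "mse") {
    stop("linear head requires loss = 'mse'")
  }
  codes <- if (is.matrix(x)) x else seqs_to_codes(x, model$spec$input_length)
  vcodes <- if (is.matrix(val_x)) val_x else seqs_to_codes(val_x, model$spec$input_length)
  if (ncol(codes) != length(y)) stop("x/y size mismatch")
  if (ncol(vcodes) != length(val_y)) stop("val_x/val_y size mismatch")
  fit <- cpp_cnn_train(model$params, .arch_for_cpp(model), codes,
                       as.numeric(y), vcodes, as.numeric(val_y),
                       config$loss, config$learning_rate, config$batch_size,
                       config$patience, config$max_epochs, config$seed)
  if (identical(fit$status, "nan"))
    stop("training aborted: loss became non-finite (try a lower learning rate)")
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = unlist(fit$train_loss),
                              val_loss = unlist(fit$val_loss))
  model$meta$trained <- TRUE
  model$meta$best_epoch <- fit$best_epoch
  model$meta$best_val_loss <- fit$best_val_loss
  model$meta$stop_reason <- fit$status
  model$meta$train_config <- config
  model
}

#' Predict with a sequence model
#'
#' @param object A trained (or untrained) \code{cnn_model}.
#' @param newdata Character vector of sequences of the model's input length,
#'   or an integer code matrix (rows = positions).
#' @param type "response" for the model output (probability for sigmoid
#'   heads), "raw" for the pre-activation score (logit).
#' @param batch Prediction batch size.
#' @param ... Unused.
#' @return Numeric vector of per-sequence scores.
#' @export
predict.cnn_model <- function(object, newdata, type = c("response", "raw"),
                              batch = 256L, ...) {
  type <- match.arg(type)
  codes <- if (is.matrix(newdata)) newdata
           else seqs_to_codes(newdata, object$spec$input_length)
  if (nrow(codes) != object$spec$input_length)
    stop(sprintf("input length %d does not match model input length %d",
                 nrow(codes), object$spec$input_length))
  if (type == "raw" && object$spec$head == "sigmoid") {
    # one-hot densify and use the raw (pre-sigmoid) path
    X <- matrix(0, 4, length(codes))
    keep <- codes > 0
    X[cbind(codes[keep], which(keep))] <- 1
    return(cpp_cnn_predict_dense(object$params, .arch_for_cpp(object), X,
                                 raw = TRUE, batch = batch))
  }
  cpp_cnn_predict(object$params, .arch_for_cpp(object), codes, batch)
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Sequence CNN (%s head), input %d bp\n", s$head, s$input_length))
  cat(sprintf("  conv filters: %s | widths: %s | dense: %s | dropout %.2f\n",
              paste(s$conv_filters, collapse = ","),
              paste(s$conv_widths, collapse = ","),
              paste(s$dense_units, collapse = ","), s$dropout))
  cat(sprintf("  trainable parameters: %d\n", n_params(x)))
  if (isTRUE(x$meta$trained)) {
    cat(sprintf("  trained: best epoch %d, best val loss %.4g (%s)\n",
                x$meta$best_epoch, x$meta$best_val_loss, x$meta$stop_reason))
    if (!is.na(x$meta$metric))
      cat(sprintf("  held-out metric: %.4f (converged: %s)\n",
                  x$meta$metric, x$meta$converged))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.cnn_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.cnn_model <- function(object, ...) object$params

#' @export
plot.cnn_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Filter replicate models by the convergence rule
#'
#' Replicates that failed to converge are dropped: regression replicates with
#' held-out test-set Pearson correlation <= 0.1, classification replicates
#' with held-out ROC AUC <= 0.7. Each model must carry its held-out metric
#' in \code{meta$metric} (set by the ensemble trainers, or manually).
#'
#' @param models List of trained \code{cnn_model}s with \code{meta$metric}.
#' @param task "regression" or "classification".
#' @param threshold Convergence cutoff; defaults to 0.1 (PCC) for regression
#'   and 0.7 (AUC) for classification.
#' @return The converged sublist (models annotated \code{meta$converged}).
#' @export
convergence_filter <- function(models, task = c("regression", "classification"),
                               threshold = NULL) {
  task <- match.arg(task)
  if (is.null(threshold)) threshold <- if (task == "regression") 0.1 else 0.7
  metrics <- vapply(models, function(m) m$meta$metric, numeric(1))
  if (any(is.na(metrics))) stop("all models must carry meta$metric")
  keep <- metrics > threshold  # strict: metric <= threshold is dropped
  out <- models[keep]
  out <- lapply(out, function(m) { m$meta$converged <- TRUE; m })
  if (length(out) == 0)
    stop(sprintf("no converged replicate (all %s metrics <= %.2f)",
                 if (task == "regression") "PCC" else "AUC", threshold))
  out
}

#' Bundle replicate models into a prediction ensemble
#'
#' Predictions of an ensemble are the arithmetic mean over its (converged)
#' replicate models.
#'
#' @param models Non-empty list of \code{cnn_model}s with identical
#'   architecture.
#' @return An object of class \code{cnn_ensemble}.
#' @export
cnn_ensemble <- function(models) {
  if (length(models) < 1) stop("ensemble needs at least one model")
  specs <- lapply(models, function(m) m$spec[c("input_length", "conv_filters",
                                               "conv_widths", "dense_units", "head")])
  if (!all(vapply(specs, identical, logical(1), y = specs[[1]])))
    stop("ensemble members must share one architecture")
  structure(list(models = models, spec = models[[1]]$spec),
            class = "cnn_ensemble")
}

#' @export
print.cnn_ensemble <- function(x, ...) {
  cat(sprintf("CNN ensemble of %d replicate model(s), %s head\n",
              length(x$models), x$spec$head))
  invisible(x)
}

#' Ensemble prediction: mean over converged replicates
#'
#' @param object A \code{cnn_ensemble}.
#' @param newdata Sequences or code matrix, as for \code{predict.cnn_model}.
#' @param ... Passed to the member predict method.
#' @return Numeric vector of mean per-sequence scores.
#' @export
predict.cnn_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$models, function(m) predict(m, newdata, ...),
                  numeric(if (is.matrix(newdata)) ncol(newdata) else length(newdata)))
  if (is.null(dim(preds))) return(mean(preds))
  rowMeans(preds)
}

#' Genome-wide tiled prediction
#'
#' Scores 1,001-bp windows tiled at the given stride across each chromosome
#' and averages the window predictions per nucleotide to obtain a genome-wide
#' coverage track. Bases covered by no window are NA.
#'
#' @param model A \code{cnn_model} or \code{cnn_ensemble}.
#' @param genome Named character vector of chromosome sequences.
#' @param stride Tiling stride in bp (default 20).
#' @param batch Prediction batch size.
#' @return Coverage track: named list of per-base numeric vectors (NA where
#'   uncovered).
#' @export
predict_genome <- function(model, genome, stride = 20L, batch = 256L) {
  validate_genome(genome)
  input_length <- model$spec$input_length
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    if (L < input_length) {
      out[[chrom]] <- rep(NA_real_, L)
      next
    }
    starts <- seq(1L, L - input_length + 1L, by = stride)
    seqs <- substring(genome[[chrom]], starts, starts + input_length - 1L)
    preds <- predict(model, seqs, batch = batch)
    acc <- numeric(L + 1L)
    cnt <- numeric(L + 1L)
    for (i in seq_along(starts)) {
      acc[starts[i]] <- acc[starts[i]] + preds[i]
      acc[starts[i] + input_length] <- acc[starts[i] + input_length] - preds[i]
      cnt[starts[i]] <- cnt[starts[i]] + 1
      cnt[starts[i] + input_length] <- cnt[starts[i] + input_length] - 1
    }
    acc <- cumsum(acc)[seq_len(L)]
    cnt <- cumsum(cnt)[seq_len(L)]
    v <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
    out[[chrom]] <- v
  }
  out
}

#' Pearson correlation coefficient
#'
#' Thin validated wrapper around \code{stats::cor} used for genome-wide
#' model evaluation.
#'
#' @param x,y Equal-length numeric vectors (length >= 2, non-constant).
#' @return PCC in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for constant vectors")
  stats::cor(x, y, method = "pearson")
}

#' Save a model with a sidecar JSON manifest
#'
#' Writes the model in R's native serialization plus a human-readable
#' \code{<path>.json} manifest (architecture, training configuration,
#' held-out metric, convergence flag).
#'
#' @param model \code{cnn_model}.
#' @param path Output path (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  manifest <- list(
    class = class(model),
    spec = model$spec[c("input_length", "conv_filters", "conv_widths",
                        "dense_units", "dropout", "head")],
    meta = model$meta[setdiff(names(model$meta), "train_config")],
    train_config = if (!is.null(model$meta$train_config))
      unclass(model$meta$train_config),
    n_params = n_params(model),
    auc_definition = "ROC"
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by \code{save_model}
#' @param path RDS path.
#' @return \code{cnn_model}.
#' @export
load_model <- function(path) readRDS(path)

# seed the RNG for the calling function's lifetime, then restore state
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}
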
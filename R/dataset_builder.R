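#' Tile a genome into fixed-length windows
#'
#' Windows of \code{window_len} bp at a fixed stride per chromosome; a
#' chromosome of length L yields floor((L - window_len) / stride) + 1
#' windows (zero when L < window_len).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param window_len Window length in bp (default 1001).
#' @param stride Stride in bp (default 50).
#' @return GRanges of tiles in genome order.
#' @export
tile_genome <- function(genome, window_len = 1001L, stride = 50L) {
  validate_genome(genome)
  stopifnot(window_len >= 1, stride >= 1)
  lens <- genome_seqlengths(genome)
  grs <- lapply(names(genome), function(chrom) {
    L <- lens[[chrom]]
    if (L < window_len) return(NULL)
    starts <- seq(1L, L - window_len + 1L, by = stride)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts,
                                                   width = window_len))
  })
  grs <- grs[!vapply(grs, is.null, logical(1))]
  if (!length(grs)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(grs)))
}

# per-window mean of the track over the central `central` bases
.central_ranges <- function(gr, central) {
  w <- GenomicRanges::width(gr)
  if (any(w < central)) stop("window shorter than central region")
  off <- (w - central) %/% 2L
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
    IRanges::IRanges(GenomicRanges::start(gr) + off, width = central))
}

#' Mean coverage over the central bases of windows
#'
#' @param track Coverage track (named list of per-base vectors).
#' @param gr Windows (GRanges).
#' @param central Width of the central region (default 201).
#' @return Numeric vector of central means.
#' @export
window_central_mean <- function(track, gr, central = 201L) {
  cgr <- .central_ranges(gr, central)
  chroms <- as.character(GenomicRanges::seqnames(cgr))
  unknown <- setdiff(unique(chroms), names(track))
  if (length(unknown)) stop("track missing chromosome(s): ",
                            paste(unknown, collapse = ", "))
  out <- numeric(length(cgr))
  starts <- GenomicRanges::start(cgr)
  ends <- GenomicRanges::end(cgr)
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- track[[chrom]]
    if (any(starts[idx] < 1L) || any(ends[idx] > length(v)))
      stop("interval outside track bounds on ", chrom)
    cs <- cumsum(c(0, v))
    out[idx] <- (cs[ends[idx] + 1L] - cs[starts[idx]]) / central
  }
  out
}

#' Log accessibility signal of tiled windows
#'
#' The regression target: natural log of the mean depth-normalized coverage
#' over the central 201 bp of each 1,001-bp window, with a small pseudocount
#' inside the log guarding all-zero windows.
#'
#' @param track Coverage track.
#' @param gr Windows.
#' @param central Central width (default 201).
#' @param pseudocount Added inside the log (default 1e-3; 0 reproduces the
#'   bare log mean).
#' @return Numeric vector of log signals.
#' @export
window_signal <- function(track, gr, central = 201L, pseudocount = 1e-3) {
  log(window_central_mean(track, gr, central) + pseudocount)
}

# fraction of N per sequence
.n_fraction <- function(seqs) {
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  n_count / nchar(seqs)
}

#' Select the accessibility-regression training windows
#'
#' Reproduces the training-set construction: tiles whose central 151 bp lie
#' entirely within any peak re-centred to 301 bp around its midpoint are
#' kept; \code{n_random} additional windows are added by seeded stratified
#' sampling over ten equal-width bins of the (tissue-averaged) central-mean
#' signal; windows with a zero pre-log central mean in any tissue and
#' windows whose target falls below the 0.01 or above the 0.999 empirical
#' quantile of any tissue's targets are then dropped. Windows with more than
#' 10 percent N are excluded up front.
#'
#' @param tiles GRanges of candidate windows (from \code{\link{tile_genome}}).
#' @param peaks GRanges of peaks combined over all tissues (or a list of
#'   GRanges, merged here).
#' @param tracks Named list (per tissue) of coverage tracks.
#' @param genome Genome assembly (for sequence/N content).
#' @param n_random Number of random windows to add.
#' @param seed Seed for the random-window sampling.
#' @param pseudocount Passed to \code{\link{window_signal}}.
#' @param max_n_frac Maximum tolerated N fraction per window.
#' @return A \code{regression_dataset} (un-augmented, folds unassigned).
#' @export
select_training_windows <- function(tiles, peaks, tracks, genome,
                                    n_random = 2000L, seed = 1L,
                                    pseudocount = 1e-3, max_n_frac = 0.1) {
  if (is.list(peaks) && !inherits(peaks, "GRanges"))
    peaks <- suppressWarnings(do.call(c, unname(peaks)))
  tissues <- names(tracks)
  seqs <- interval_sequences(genome, tiles)
  keep_n <- .n_fraction(seqs) <= max_n_frac
  tiles <- tiles[keep_n]
  seqs <- seqs[keep_n]

  # re-centre every peak to 301 bp around its midpoint
  mids <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  rec <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(1L, mids - 150L), width = 301L))
  central151 <- .central_ranges(tiles, 151L)
  in_peak <- GenomicRanges::countOverlaps(central151, rec,
                                          type = "within") > 0

  means <- vapply(tissues, function(t)
    window_central_mean(tracks[[t]], tiles), numeric(length(tiles)))
  if (length(tiles) == 1) means <- matrix(means, nrow = 1)

  # stratified random additions over the signal range
  pool <- which(!in_peak)
  if (n_random > length(pool))
    stop(sprintf("n_random = %d exceeds the %d available non-peak tiles",
                 n_random, length(pool)))
  sel_random <- integer(0)
  if (n_random > 0) {
    local_seed(seed)
    m <- rowMeans(means)[pool]
    bins <- cut(m, breaks = 10L, labels = FALSE, include.lowest = TRUE)
    per_bin <- split(pool, bins)
    share <- ceiling(n_random / length(per_bin))
    sel_random <- unlist(lapply(per_bin, function(ix)
      if (length(ix) <= share) ix else sample(ix, share)), use.names = FALSE)
    if (length(sel_random) > n_random)
      sel_random <- sample(sel_random, n_random)
    else if (length(sel_random) < n_random) {
      rest <- setdiff(pool, sel_random)
      sel_random <- c(sel_random, sample(rest, n_random - length(sel_random)))
    }
  }
  sel <- sort(unique(c(which(in_peak), sel_random)))
  origin <- ifelse(sel %in% which(in_peak), "peak", "random")

  tiles <- tiles[sel]
  seqs <- seqs[sel]
  means <- means[sel, , drop = FALSE]
  targets <- log(means + pseudocount)
  colnames(targets) <- tissues

  # non-zero signal in every tissue
  keep <- rowSums(means == 0) == 0
  # per-tissue outlier quantiles (linear interpolation, candidate set)
  for (t in tissues) {
    q <- stats::quantile(targets[, t], c(0.01, 0.999), names = FALSE)
    keep <- keep & targets[, t] >= q[1] & targets[, t] <= q[2]
  }
  tiles <- tiles[keep]
  new_regression_dataset(
    windows = data.frame(
      chrom = as.character(GenomicRanges::seqnames(tiles)),
      start = GenomicRanges::start(tiles),
      end = GenomicRanges::end(tiles),
      strand = "+",
      origin = origin[keep],
      source_id = seq_len(sum(keep)),
      stringsAsFactors = FALSE),
    seq = seqs[keep],
    targets = targets[keep, , drop = FALSE])
}

new_regression_dataset <- function(windows, seq, targets, fold = NULL,
                                   augmented = FALSE, fold_plan = NULL) {
  structure(list(windows = windows, seq = unname(seq), targets = targets,
                 fold = fold, augmented = augmented, fold_plan = fold_plan),
            class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("Regression dataset: %d windows%s, %d tissue target(s)\n",
              nrow(x$windows),
              if (x$augmented) " (reverse-complement augmented)" else "",
              ncol(x$targets)))
  if (!is.null(x$fold))
    cat(sprintf("  folds: %s\n", paste(sort(unique(x$fold)), collapse = ",")))
  invisible(x)
}

#' Reverse-complement augmentation
#'
#' Doubles a dataset by adding the reverse complement of every window with
#' identical targets, fold and source id. Augmenting twice is an error.
#'
#' @param dataset A \code{regression_dataset} (un-augmented).
#' @return The augmented dataset (size exactly doubled).
#' @export
augment_reverse_complement <- function(dataset) {
  stopifnot(inherits(dataset, "regression_dataset"))
  if (dataset$augmented) stop("dataset is already reverse-complement augmented")
  w2 <- dataset$windows
  w2$strand <- "-"
  new_regression_dataset(
    windows = rbind(dataset$windows, w2),
    seq = c(dataset$seq, reverse_complement(dataset$seq)),
    targets = rbind(dataset$targets, dataset$targets),
    fold = if (!is.null(dataset$fold)) c(dataset$fold, dataset$fold),
    augmented = TRUE,
    fold_plan = dataset$fold_plan)
}

#' Chromosome-half cross-validation plan
#'
#' Splits every chromosome at its midpoint into two halves and assigns
#' halves to folds by seeded round-robin over halves ordered by decreasing
#' length, giving fold sizes as equal as possible. The rotation schedule
#' uses each fold exactly once as test set, with the next fold as
#' validation and the remaining folds as training.
#'
#' @param genome Genome assembly.
#' @param n_folds Number of folds (default 10); requires at least
#'   \code{n_folds} chromosome halves.
#' @param seed Seed for the round-robin fold order.
#' @return An object of class \code{fold_plan}: \code{halves} (data.frame
#'   chrom, start, end, fold), \code{rotations} (data.frame test, val),
#'   \code{n_folds}.
#' @export
fold_plan <- function(genome, n_folds = 10L, seed = 1L) {
  validate_genome(genome)
  lens <- genome_seqlengths(genome)
  halves <- do.call(rbind, lapply(names(lens), function(chrom) {
    h <- lens[[chrom]] %/% 2L
    data.frame(chrom = chrom,
               start = c(1L, h + 1L),
               end = c(h, lens[[chrom]]),
               stringsAsFactors = FALSE)
  }))
  halves <- halves[halves$end >= halves$start, ]
  if (nrow(halves) < n_folds)
    stop(sprintf("need at least %d chromosome halves for %d folds; have %d",
                 n_folds, n_folds, nrow(halves)))
  halves <- halves[order(-(halves$end - halves$start), halves$chrom,
                         halves$start), ]
  local_seed(seed)
  order_folds <- sample.int(n_folds)
  halves$fold <- rep(order_folds, length.out = nrow(halves))
  rotations <- data.frame(test = seq_len(n_folds),
                          val = seq_len(n_folds) %% n_folds + 1L)
  structure(list(halves = halves[order(halves$chrom, halves$start), ],
                 rotations = rotations, n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Chromosome-half fold plan: %d folds over %d halves\n",
              x$n_folds, nrow(x$halves)))
  print(x$halves, row.names = FALSE)
  invisible(x)
}

#' Fold membership of intervals under a fold plan
#'
#' An interval belongs to the fold of the chromosome half containing its
#' midpoint; a midpoint exactly at the split boundary goes to the left half.
#'
#' @param plan A \code{fold_plan}.
#' @param chrom,start,end Interval coordinates (1-based closed), vectorized.
#' @return Integer vector of fold ids.
#' @export
fold_of_intervals <- function(plan, chrom, start, end) {
  stopifnot(inherits(plan, "fold_plan"))
  mid <- (start + end) %/% 2L
  h <- plan$halves
  left <- h[h$start == 1L, ]
  right <- h[h$start > 1L, ]
  unknown <- setdiff(unique(chrom), left$chrom)
  if (length(unknown)) stop("chromosome(s) not in fold plan: ",
                            paste(unknown, collapse = ", "))
  li <- match(chrom, left$chrom)
  ri <- match(chrom, right$chrom)
  # midpoint exactly at the split boundary goes to the left half
  use_left <- mid <= left$end[li] | is.na(ri)
  ifelse(use_left, left$fold[li], right$fold[ri])
}

#' Assign cross-validation folds to a dataset
#'
#' @param dataset A \code{regression_dataset}.
#' @param plan A \code{fold_plan} (or a genome, from which a plan is built).
#' @param n_folds,seed Used when \code{plan} is a genome.
#' @return The dataset with \code{fold} filled and the plan attached.
#' @export
assign_folds <- function(dataset, plan, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "regression_dataset"))
  if (!inherits(plan, "fold_plan")) plan <- fold_plan(plan, n_folds, seed)
  dataset$fold <- fold_of_intervals(plan, dataset$windows$chrom,
                                    dataset$windows$start,
                                    dataset$windows$end)
  dataset$fold_plan <- plan
  dataset
}

#' Train/validation/test indices for one cross-validation rotation
#'
#' @param dataset Dataset with folds assigned.
#' @param test_fold Fold id serving as the held-out test set.
#' @param originals_only_test Use only non-augmented windows in the test set.
#' @return List of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
dataset_split <- function(dataset, test_fold, originals_only_test = TRUE) {
  stopifnot(!is.null(dataset$fold), !is.null(dataset$fold_plan))
  rot <- dataset$fold_plan$rotations
  val_fold <- rot$val[rot$test == test_fold]
  if (!length(val_fold)) stop("unknown test fold: ", test_fold)
  test <- which(dataset$fold == test_fold)
  if (originals_only_test && dataset$augmented)
    test <- test[dataset$windows$strand[test] == "+"]
  list(train = which(!dataset$fold %in% c(test_fold, val_fold)),
       val = which(dataset$fold == val_fold),
       test = test)
}

#' Build the full accessibility-regression dataset for a synthetic world
#'
#' Composes tiling, window selection, fold assignment and
#' reverse-complement augmentation with the stage-one defaults.
#'
#' @param world A \code{synthetic_world} (or list from
#'   \code{\link{read_world_files}}).
#' @param n_random Random windows to add (default 2000).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for sampling and fold order.
#' @return An augmented \code{regression_dataset} with folds assigned.
#' @export
build_regression_dataset <- function(world, n_random = 2000L, n_folds = 10L,
                                     seed = 1L) {
  tiles <- tile_genome(world$genome)
  ds <- select_training_windows(tiles, world$peaks, world$tracks,
                                world$genome, n_random = n_random,
                                seed = seed)
  ds <- assign_folds(ds, world$genome, n_folds = n_folds, seed = seed)
  augment_reverse_complement(ds)
}

#' Write a regression dataset as a TSV table
#'
#' Columns: chrom, start, end, strand, origin, source_id, fold and one
#' target column per tissue. Sequences are regenerable from the genome
#' FASTA and are not stored.
#'
#' @param dataset \code{regression_dataset}.
#' @param path Output TSV path.
#' @export
write_dataset_table <- function(dataset, path) {
  df <- cbind(dataset$windows,
              fold = if (is.null(dataset$fold)) NA_integer_ else dataset$fold,
              as.data.frame(dataset$targets))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
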
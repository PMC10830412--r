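#' Build the confident evaluation set for activity classification
#'
#' Positives are accessibility peaks that overlap a tile active in the
#' tissue by at least 201 bp. Negatives are peaks overlapping inactive
#' tiles by at least 201 bp, plus the inactive tiles themselves. Evaluation
#' always uses original (non-augmented) sequences.
#'
#' @param peaks GRanges of the tissue's accessibility peaks.
#' @param active_tiles GRanges of tiles active in the tissue.
#' @param inactive_tiles GRanges of tiles inactive in the tissue.
#' @param genome Optional genome assembly; when given, each element is
#'   represented by the 1,001-bp window centred on its midpoint and the
#'   sequence is attached.
#' @param min_overlap Minimum peak/tile overlap (default 201 bp).
#' @param window_len Evaluation window length when extracting sequences.
#' @return An \code{eval_set}: data.frame with chrom, start, end, label
#'   (1/0), provenance, and seq when a genome is supplied.
#' @export
build_eval_set <- function(peaks, active_tiles, inactive_tiles,
                           genome = NULL, min_overlap = 201L,
                           window_len = 1001L) {
  in_active <- GenomicRanges::countOverlaps(peaks, active_tiles,
                                            minoverlap = min_overlap) > 0
  in_inactive <- GenomicRanges::countOverlaps(peaks, inactive_tiles,
                                              minoverlap = min_overlap) > 0
  pos <- peaks[in_active]
  if (!length(pos)) stop("no positive elements: no peak overlaps an active tile")
  neg_peaks <- peaks[!in_active & in_inactive]
  .as_df <- function(gr, label, provenance) {
    if (!length(gr)) return(NULL)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               label = label, provenance = provenance,
               stringsAsFactors = FALSE)
  }
  df <- rbind(.as_df(pos, 1, "peak-in-active-tile"),
              .as_df(neg_peaks, 0, "peak-in-inactive-tile"),
              .as_df(inactive_tiles, 0, "other-inactive"))
  rownames(df) <- NULL
  if (!is.null(genome)) {
    lens <- genome_seqlengths(genome)
    mid <- (df$start + df$end) %/% 2L
    ws <- pmax(1L, pmin(mid - (window_len %/% 2L),
                        lens[df$chrom] - window_len + 1L))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(ws, width = window_len))
    df$seq <- interval_sequences(genome, gr)
  }
  class(df) <- c("eval_set", class(df))
  df
}

#' Area under the precision-recall curve
#'
#' Step integration over the distinct score thresholds in decreasing order:
#' AUPRC = sum over thresholds of (recall step) x precision. Invariant
#' under strictly monotone transforms of the scores; the no-skill baseline
#' equals the positive-class prevalence.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("AUPRC undefined: labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: metrics are evaluated once per distinct threshold
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_last]
  n_pred <- grp_last
  precision <- tp / n_pred
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics at a fixed threshold
#'
#' AUPRC by precision-recall step integration, plus accuracy and F1 score
#' at the given probability cutoff (predictions with score >= threshold
#' count as positive).
#'
#' @param scores Prediction scores.
#' @param labels 0/1 truth labels.
#' @param threshold Decision cutoff (default 0.5).
#' @return Named list: auprc, accuracy, f1, threshold, and the confusion
#'   counts (tp, fp, fn, tn).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  list(auprc = auprc(scores, labels),
       accuracy = (tp + tn) / length(labels),
       f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn),
       threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Positive predictive value across prediction thresholds
#'
#' For each threshold t, predictions are the sequences scoring >= t; the
#' PPV is the fraction of truly active sequences among them. Estimates
#' based on more than 50 positive predictions are flagged confident
#' (solid-line estimates); PPV is NA where there are no predictions.
#'
#' @param scores Prediction scores.
#' @param labels 0/1 truth labels.
#' @param thresholds Increasing vector of thresholds in [0, 1].
#' @param confident_min Predictions required for a confident estimate
#'   (strictly more than; default 50).
#' @return data.frame of class \code{ppv_curve}: threshold, ppv,
#'   n_predictions, confident.
#' @export
ppv_curve <- function(scores, labels, thresholds = seq(0, 1, by = 0.05),
                      confident_min = 50L) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted increasing")
  labels <- as.numeric(labels)
  rows <- lapply(thresholds, function(t) {
    hit <- scores >= t
    n <- sum(hit)
    data.frame(threshold = t,
               ppv = if (n == 0) NA_real_ else sum(labels[hit] == 1) / n,
               n_predictions = n,
               confident = n > confident_min)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ppv_curve", class(out))
  out
}

#' @export
plot.ppv_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$ppv * 100, type = "n",
                 xlab = "prediction threshold", ylab = "PPV (%)",
                 ylim = c(0, 100), ...)
  graphics::lines(x$threshold, ifelse(x$confident, x$ppv * 100, NA), lty = 1)
  graphics::lines(x$threshold, ifelse(!x$confident, x$ppv * 100, NA), lty = 2)
  invisible(x)
}

#' Enhancers near a marker-gene transcription start site
#'
#' Keeps elements whose midpoint lies within +/- \code{flank} bp of the TSS
#' (inclusive bounds).
#'
#' @param enhancers GRanges of enhancer elements.
#' @param tss_chrom Chromosome of the TSS.
#' @param tss_pos TSS position (1-based).
#' @param flank Window half-width in bp (default 50,000).
#' @return The subset GRanges.
#' @export
marker_locus_subset <- function(enhancers, tss_chrom, tss_pos,
                                flank = 50000L) {
  mid <- (GenomicRanges::start(enhancers) + GenomicRanges::end(enhancers)) %/% 2L
  keep <- as.character(GenomicRanges::seqnames(enhancers)) == tss_chrom &
    abs(mid - tss_pos) <= flank
  enhancers[keep]
}
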
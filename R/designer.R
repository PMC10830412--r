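#' Random candidate core sequences
#'
#' Zero-order Markov (i.i.d.) sequences of the given base composition,
#' mirroring random candidate generation for enhancer design (501-bp cores
#' by default, uniform composition).
#'
#' @param n Number of sequences.
#' @param length Sequence length (default 501).
#' @param composition Base probabilities (A, C, G, T; sums to 1).
#' @param seed Integer seed.
#' @return Character vector of n sequences.
#' @export
generate_random_cores <- function(n, length = 501L,
                                  composition = c(0.25, 0.25, 0.25, 0.25),
                                  seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-8, n >= 0)
  local_seed(seed)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(bases, length, replace = TRUE, prob = composition),
          collapse = ""), character(1))
}

#' Flank a core sequence to the model input length
#'
#' Concatenates left flank + core + right flank. With fixed flanks the core
#' sits verbatim at positions 251..751 of the 1,001-bp construct; otherwise
#' random uniform flanks are drawn from the seed.
#'
#' @param core Character vector of 501-bp cores.
#' @param left,right Optional fixed flanks (250 bp each).
#' @param flank_len Flank length (default 250).
#' @param seed Seed for random flanks.
#' @return Character vector of flanked sequences (1,001 bp).
#' @export
add_flanks <- function(core, left = NULL, right = NULL, flank_len = 250L,
                       seed = 1L) {
  fixed <- !is.null(left) || !is.null(right)
  if (fixed) {
    if (is.null(left) || is.null(right))
      stop("supply both flanks or neither")
    if (nchar(left) != flank_len || nchar(right) != flank_len)
      stop(sprintf("fixed flanks must be %d bp", flank_len))
    return(paste0(left, core, right))
  }
  flanks <- generate_random_cores(2L * length(core), length = flank_len,
                                  seed = seed)
  paste0(flanks[seq_along(core)], core,
         flanks[length(core) + seq_along(core)])
}

#' Selection policy for candidate screening
#'
#' @param activity_threshold Minimum target-tissue activity probability.
#' @param off_target_ceiling Maximum allowed activity in any other tissue
#'   (must be below the activity threshold).
#' @param accessibility_quantile Candidates must reach this quantile of the
#'   screened batch's target-tissue accessibility scores.
#' @param max_candidates Candidates kept after ranking.
#' @param seed Seed for the flanking of screened candidates.
#' @return Object of class \code{selection_policy}.
#' @export
selection_policy <- function(activity_threshold = 0.8,
                             off_target_ceiling = 0.2,
                             accessibility_quantile = 0.8,
                             max_candidates = 8L, seed = 1L) {
  stopifnot(activity_threshold >= 0, activity_threshold <= 1,
            off_target_ceiling >= 0, off_target_ceiling <= 1,
            accessibility_quantile >= 0, accessibility_quantile <= 1)
  if (activity_threshold <= off_target_ceiling)
    stop("activity_threshold must exceed off_target_ceiling")
  structure(list(activity_threshold = activity_threshold,
                 off_target_ceiling = off_target_ceiling,
                 accessibility_quantile = accessibility_quantile,
                 max_candidates = as.integer(max_candidates),
                 seed = as.integer(seed)),
            class = "selection_policy")
}

#' Screen random cores for tissue-specific candidates
#'
#' Flanks every core with random sequence to the model input length, scores
#' accessibility (target tissue) and activity (all tissues), and keeps
#' candidates with target activity >= threshold, every off-target activity
#' <= ceiling and accessibility at or above the batch quantile. Survivors
#' are ranked by target activity, ties broken by lower maximal off-target
#' activity, then input order. An empty result is returned (with summary
#' statistics attached), not an error.
#'
#' @param cores Character vector of 501-bp candidate cores.
#' @param activity_models Named list (per tissue) of activity models or
#'   ensembles; must include the target tissue.
#' @param accessibility_model Accessibility model/ensemble for the target
#'   tissue.
#' @param target_tissue Tissue to design for.
#' @param policy A \code{\link{selection_policy}}.
#' @return data.frame of class \code{candidate_set}: core, sequence,
#'   per-tissue activity columns, accessibility, rank.
#' @export
screen_candidates <- function(cores, activity_models, accessibility_model,
                              target_tissue, policy = selection_policy()) {
  if (!target_tissue %in% names(activity_models))
    stop("no activity model for target tissue ", target_tissue)
  seqs <- add_flanks(cores, seed = policy$seed)
  act <- vapply(activity_models, function(m) predict(m, seqs),
                numeric(length(seqs)))
  if (length(seqs) == 1) act <- matrix(act, nrow = 1,
                                       dimnames = list(NULL, names(activity_models)))
  access <- predict(accessibility_model, seqs)
  access_thr <- stats::quantile(access, policy$accessibility_quantile,
                                names = FALSE)
  target <- act[, target_tissue]
  off <- act[, setdiff(colnames(act), target_tissue), drop = FALSE]
  max_off <- if (ncol(off)) apply(off, 1, max) else rep(0, length(seqs))
  keep <- target >= policy$activity_threshold &
    max_off <= policy$off_target_ceiling & access >= access_thr
  df <- data.frame(core = cores, sequence = seqs, accessibility = access,
                   stringsAsFactors = FALSE)
  for (t in colnames(act)) df[[paste0("activity_", t)]] <- act[, t]
  df$max_off_target <- max_off
  df <- df[keep, , drop = FALSE]
  ord <- order(-df[[paste0("activity_", target_tissue)]], df$max_off_target,
               as.integer(rownames(df)))
  df <- df[ord, , drop = FALSE]
  if (nrow(df) > policy$max_candidates)
    df <- df[seq_len(policy$max_candidates), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "summary") <- list(
    n_screened = length(cores), n_passing = sum(keep),
    accessibility_threshold = access_thr, target_tissue = target_tissue)
  class(df) <- c("candidate_set", class(df))
  df
}

#' @export
print.candidate_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Candidate screen for %s: %d/%d passed the policy, %d kept\n",
              s$target_tissue, s$n_passing, s$n_screened, nrow(x)))
  if (nrow(x)) {
    show <- x[, c("rank", "accessibility",
                  grep("^activity_", names(x), value = TRUE))]
    print(utils::head(as.data.frame(show), 10), row.names = FALSE)
  }
  invisible(x)
}

#' Robustness of a candidate core to its flanking context
#'
#' Scores the core inside \code{n_flanks} different random flank contexts
#' and summarizes min/median/max; the candidate passes when the minimum
#' stays above \code{pass_frac} of its original selection score.
#'
#' @param core 501-bp core sequence.
#' @param model Activity model or ensemble.
#' @param n_flanks Number of random flank contexts (default 100).
#' @param seed Seed for the flanks.
#' @param reference_score Original selection score of the candidate
#'   (defaults to the median of the resampled scores).
#' @param pass_frac Fraction of the reference the minimum must reach.
#' @return List: min, median, max, scores, pass.
#' @export
flank_robustness <- function(core, model, n_flanks = 100L, seed = 1L,
                             reference_score = NULL, pass_frac = 0.8) {
  seqs <- add_flanks(rep(core, n_flanks), seed = seed)
  scores <- predict(model, seqs)
  if (is.null(reference_score)) reference_score <- stats::median(scores)
  list(min = min(scores), median = stats::median(scores), max = max(scores),
       scores = scores, reference = reference_score,
       pass = min(scores) >= pass_frac * reference_score)
}

#' Percentile of a score against a random background
#'
#' 100 x the fraction of background scores strictly below the score.
#'
#' @param score Numeric score(s).
#' @param background_scores Non-empty numeric background distribution.
#' @return Percentile(s) in [0, 100].
#' @export
percentile_vs_background <- function(score, background_scores) {
  if (!length(background_scores)) stop("background must be non-empty")
  vapply(score, function(s)
    100 * mean(background_scores < s), numeric(1))
}

#' Final activity scores of a candidate in its reporter context
#'
#' Places the 501-bp core within the fixed flanks of the reporter construct
#' and averages the activity predictions of the ten fold models.
#'
#' @param core 501-bp core.
#' @param left,right Construct flank sequences (250 bp each).
#' @param fold_models List of per-fold activity models (one per fold).
#' @return Mean predicted activity across folds.
#' @export
final_scores <- function(core, left, right, fold_models) {
  missing <- which(vapply(fold_models, is.null, logical(1)))
  if (length(missing))
    stop("missing fold model(s): ", paste(missing, collapse = ", "))
  seq <- add_flanks(core, left = left, right = right)
  mean(vapply(fold_models, function(m) predict(m, seq), numeric(1)))
}
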
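#' Configuration for a synthetic regulatory genome
#'
#' Defines the ground truth of a small synthetic world: a random background
#' genome with tissue-specific motifs planted at known positions, per-tissue
#' accessibility tracks that are a smoothed monotone function of planted
#' motif content plus multiplicative lognormal noise, threshold-derived
#' accessibility peaks, and an in-vivo-style activity table in which a
#' fragment is active in a tissue when some 501-bp core contains at least
#' \code{activity_rule} planted instances of that tissue's motif.
#'
#' The default world has five 100-kb chromosomes (ten chromosome halves, so
#' the ten-fold chromosome-half cross-validation plan is exactly one half per
#' fold) and three tissues with distinct 8-bp near-consensus motifs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param tissues Character vector of tissue names.
#' @param motifs Named list (per tissue) of PWMs: positions x 4 probability
#'   matrices (columns A,C,G,T; rows sum to 1).
#' @param plant_rate Expected planted sites per kb per tissue (> 0).
#' @param accessibility_gain Signal added per unit of smoothed site score.
#' @param baseline Baseline accessibility before noise.
#' @param noise_sd Lognormal noise scale (>= 0).
#' @param activity_rule Named integer vector (per tissue, recycled from a
#'   scalar): minimum planted-motif instances within a 501-bp core for the
#'   label "active" (>= 1).
#' @param peak_quantile Background quantile defining the peak threshold.
#' @param min_peak_len Minimum peak length after extension (bp).
#' @param frag_len Length of activity fragments (bp).
#' @param frag_stride Stride between activity fragments (bp).
#' @param composition Background base composition (A,C,G,T; sums to 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class \code{world_config}.
#' @export
world_config <- function(n_chromosomes = 5L,
                         chromosome_length = 100000L,
                         tissues = c("cns", "epidermis", "gut"),
                         motifs = NULL,
                         plant_rate = 0.75,
                         accessibility_gain = 1,
                         baseline = 1,
                         noise_sd = 0.2,
                         activity_rule = 2L,
                         peak_quantile = 0.95,
                         min_peak_len = 301L,
                         frag_len = 2001L,
                         frag_stride = 2000L,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         seed = 1L) {
  stopifnot(plant_rate > 0, noise_sd >= 0, length(tissues) >= 1,
            abs(sum(composition) - 1) < 1e-8, n_chromosomes >= 1,
            chromosome_length >= 1)
  if (is.null(motifs)) motifs <- default_motifs(tissues)
  if (!all(tissues %in% names(motifs)))
    stop("motifs must be named by tissue")
  for (m in motifs) {
    if (!is.matrix(m) || ncol(m) != 4 || any(abs(rowSums(m) - 1) > 1e-8))
      stop("each motif must be a positions x 4 probability matrix with rows summing to 1")
  }
  if (length(activity_rule) == 1) {
    activity_rule <- stats::setNames(rep(as.integer(activity_rule),
                                         length(tissues)), tissues)
  }
  if (any(activity_rule < 1)) stop("activity_rule thresholds must be >= 1")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    tissues = tissues, motifs = motifs[tissues],
    plant_rate = plant_rate, accessibility_gain = accessibility_gain,
    baseline = baseline, noise_sd = noise_sd,
    activity_rule = activity_rule[tissues],
    peak_quantile = peak_quantile, min_peak_len = as.integer(min_peak_len),
    frag_len = as.integer(frag_len), frag_stride = as.integer(frag_stride),
    composition = composition, seed = as.integer(seed)
  ), class = "world_config")
}

#' Default planted motifs for synthetic tissues
#'
#' Distinct 8-bp near-consensus PWMs (0.95 on the consensus base, the rest
#' spread uniformly), one per tissue, assigned in order. The high consensus
#' probability keeps planted instances recognizable under the package's
#' sequence-level match rule (at most one mismatch).
#'
#' @param tissues Character vector of tissue names.
#' @return Named list of positions x 4 PWMs.
#' @export
default_motifs <- function(tissues) {
  consensus <- c("GGGGTAAC", "ACCGGTTA", "TGATAAGC", "CATTGCAC", "GTCACGTA")
  if (length(tissues) > length(consensus))
    stop("provide motifs explicitly for more than ", length(consensus), " tissues")
  out <- lapply(seq_along(tissues), function(i)
    consensus_pwm(consensus[i], p = 0.95))
  names(out) <- tissues
  out
}

#' Build a near-consensus PWM from a consensus string
#'
#' @param consensus DNA string over ACGT.
#' @param p Probability mass on the consensus base (rest spread uniformly).
#' @return Positions x 4 probability matrix.
#' @export
consensus_pwm <- function(consensus, p = 0.85) {
  codes <- dna_codes(consensus)
  if (any(codes == 0)) stop("consensus must be over {A,C,G,T}")
  W <- length(codes)
  m <- matrix((1 - p) / 3, W, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(W), codes)] <- p
  m
}

# log2-odds score of an instance under a PWM vs uniform background
.pwm_instance_score <- function(pwm, codes) {
  sum(log2(pwm[cbind(seq_along(codes), codes)] / 0.25))
}

# triangular kernel of half-width hw, peak 1 at the centre
.tri_kernel <- function(hw = 100L) {
  d <- -hw:hw
  1 - abs(d) / (hw + 1)
}

# linear convolution of x with a short symmetric kernel, same length as x
.smooth_same <- function(x, kernel) {
  hw <- (length(kernel) - 1L) %/% 2L
  out <- stats::convolve(c(numeric(hw), x, numeric(hw)), rev(kernel),
                         type = "filter")
  out[seq_along(x)]
}

.runmean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate a synthetic world
#'
#' Draws the background genome i.i.d. from the configured base composition,
#' plants Poisson-distributed motif instances per tissue (overlap collisions
#' resolved by rejection, at most 100 retries per site), derives per-tissue
#' accessibility as baseline + gain x (site log-odds impulses smoothed with a
#' 200-bp triangular kernel) under multiplicative lognormal noise, calls
#' peaks as maximal runs of the locally averaged track above the
#' \code{peak_quantile} of its background distribution (extended to at least
#' \code{min_peak_len} bp), and labels non-overlapping activity fragments by
#' the planted-motif activity rule.
#'
#' @param config A \code{\link{world_config}}.
#' @return An object of class \code{synthetic_world} with elements
#'   \code{genome}, \code{tracks}, \code{peaks}, \code{activity},
#'   \code{truth} and \code{config}.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  local_seed(config$seed)
  L <- config$chromosome_length
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  bases <- c("A", "C", "G", "T")

  genome <- character(0)
  truth <- list()
  for (chrom in chrom_names) {
    seq_codes <- sample.int(4L, L, replace = TRUE, prob = config$composition)
    occupied <- logical(L)
    for (tissue in config$tissues) {
      pwm <- config$motifs[[tissue]]
      W <- nrow(pwm)
      n_sites <- stats::rpois(1, config$plant_rate * L / 1000)
      for (s in seq_len(n_sites)) {
        placed <- FALSE
        for (try in seq_len(100L)) {
          pos <- sample.int(L - W + 1L, 1)
          if (!any(occupied[pos:(pos + W - 1L)])) { placed <- TRUE; break }
        }
        if (!placed) next  # skip unplaceable site
        inst <- vapply(seq_len(W), function(j)
          sample.int(4L, 1, prob = pwm[j, ]), integer(1))
        seq_codes[pos:(pos + W - 1L)] <- inst
        occupied[pos:(pos + W - 1L)] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + W - 1L, tissue = tissue,
          score = .pwm_instance_score(pwm, inst),
          stringsAsFactors = FALSE)
      }
    }
    genome[chrom] <- paste(bases[seq_codes], collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               tissue = character(), score = numeric())

  kernel <- .tri_kernel(100L)
  tracks <- list()
  peaks <- list()
  for (tissue in config$tissues) {
    track <- list()
    clean <- list()
    for (chrom in chrom_names) {
      imp <- numeric(L)
      tsites <- truth[truth$chrom == chrom & truth$tissue == tissue, ,
                      drop = FALSE]
      if (nrow(tsites)) {
        centers <- (tsites$start + tsites$end) %/% 2L
        imp[centers] <- imp[centers] + tsites$score
      }
      sm <- if (any(imp != 0)) .smooth_same(imp, kernel) else numeric(L)
      sm[sm < 0] <- 0  # numerical fuzz from the FFT
      signal <- config$baseline + config$accessibility_gain * sm
      noise <- if (config$noise_sd > 0)
        exp(stats::rnorm(L, 0, config$noise_sd)) else 1
      track[[chrom]] <- signal * noise
      clean[[chrom]] <- sm
    }
    tracks[[tissue]] <- track
    peaks[[tissue]] <- .call_peaks(track, clean, truth, tissue, config)
  }

  activity <- .make_activity_table(chrom_names, truth, config)

  structure(list(config = config, genome = genome, tracks = tracks,
                 peaks = peaks, activity = activity, truth = truth),
            class = "synthetic_world")
}

# peak emulation: runs of the 75-bp moving average above the background
# quantile, extended to >= min_peak_len and merged
.call_peaks <- function(track, clean, truth, tissue, config) {
  out <- GenomicRanges::GRangesList()
  grs <- list()
  for (chrom in names(track)) {
    v <- .runmean(track[[chrom]], 75L)
    bg <- v[clean[[chrom]] == 0]
    if (!length(bg)) bg <- v
    thr <- stats::quantile(bg, config$peak_quantile, names = FALSE)
    above <- v > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    mid <- (runs$start + runs$end) %/% 2L
    len <- runs$end - runs$start + 1L
    ext <- pmax(config$min_peak_len - len, 0L)
    runs$start <- pmax(1L, runs$start - ceiling(ext / 2))
    runs$end <- pmin(length(v), runs$start + pmax(len, config$min_peak_len) - 1L)
    grs[[chrom]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(runs$start, runs$end))
  }
  if (!length(grs)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(suppressWarnings(do.call(c, unname(grs))))
}

# maximum number of site centres of one tissue inside any 501-bp window that
# lies within [fs, fe]
.max_core_count <- function(centers, fs, fe, core = 501L) {
  centers <- sort(centers[centers >= fs & centers <= fe])
  if (!length(centers)) return(0L)
  best <- 0L
  for (c0 in centers) {
    w0 <- min(max(c0, fs), fe - core + 1L)
    best <- max(best, sum(centers >= w0 & centers <= w0 + core - 1L))
  }
  best
}

.make_activity_table <- function(chrom_names, truth, config) {
  rows <- list()
  L <- config$chromosome_length
  for (chrom in chrom_names) {
    if (L < config$frag_len) next
    starts <- seq(1L, L - config$frag_len + 1L, by = config$frag_stride)
    for (fs in starts) {
      fe <- fs + config$frag_len - 1L
      any_active <- FALSE
      for (tissue in config$tissues) {
        tsites <- truth[truth$chrom == chrom & truth$tissue == tissue, ,
                        drop = FALSE]
        centers <- (tsites$start + tsites$end) %/% 2L
        cnt <- .max_core_count(centers, fs, fe)
        if (cnt >= config$activity_rule[[tissue]]) {
          any_active <- TRUE
          term <- sample(paste0(tissue, c("_term", "_alt_term")), 1,
                         prob = c(0.8, 0.2))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = fs, end = fe,
            stage_term = "stage13-16", tissue_term = term,
            label = "active", stringsAsFactors = FALSE)
        }
      }
      # distractor annotations exercising the stage filter downstream;
      # early-stage activity still requires some planted element
      any_site <- any(truth$chrom == chrom & truth$start >= fs &
                      truth$end <= fe)
      if (any_site && stats::runif(1) < 0.2) {
        tissue <- sample(config$tissues, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = fs, end = fe,
          stage_term = "stage4-6", tissue_term = paste0(tissue, "_term"),
          label = "active", stringsAsFactors = FALSE)
      }
      # every tested fragment appears in the table: fragments with no
      # in-range activity carry an explicit inactive observation
      if (!any_active) {
        tissue <- sample(config$tissues, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = fs, end = fe,
          stage_term = "stage13-16", tissue_term = paste0(tissue, "_term"),
          label = "inactive", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stage_term = character(), tissue_term = character(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Recompute activity labels from a world's planted-site truth
#'
#' Independent replay of the generator's activity rule: for every fragment
#' and tissue, a fragment is active when some 501-bp window inside it holds
#' at least \code{activity_rule} planted sites of the tissue. Used to verify
#' that the emitted activity table matches the ground truth.
#'
#' @param world A \code{synthetic_world}.
#' @return data.frame (chrom, start, end, tissue, active).
#' @export
recount_labels <- function(world) {
  config <- world$config
  L <- config$chromosome_length
  rows <- list()
  for (chrom in names(world$genome)) {
    if (L < config$frag_len) next
    starts <- seq(1L, L - config$frag_len + 1L, by = config$frag_stride)
    for (fs in starts) {
      for (tissue in config$tissues) {
        tsites <- world$truth[world$truth$chrom == chrom &
                              world$truth$tissue == tissue, , drop = FALSE]
        centers <- (tsites$start + tsites$end) %/% 2L
        cnt <- .max_core_count(centers, fs, fs + config$frag_len - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = fs, end = fs + config$frag_len - 1L,
          tissue = tissue, active = cnt >= config$activity_rule[[tissue]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Term map of a synthetic world
#'
#' Annotation terms that count as active evidence for each tissue, in the
#' schema consumed by \code{\link{label_records}}.
#'
#' @param config A \code{world_config} (or a \code{synthetic_world}).
#' @return Named list: per tissue, \code{list(terms = ..., exclude_terms =
#'   character(0))}.
#' @export
world_term_map <- function(config) {
  if (inherits(config, "synthetic_world")) config <- config$config
  out <- lapply(config$tissues, function(t)
    list(terms = paste0(t, c("_term", "_alt_term")),
         exclude_terms = character(0)))
  names(out) <- config$tissues
  out
}

#' Count motif matches in a sequence
#'
#' Counts positions (on both strands) within \code{max_mismatch} mismatches
#' of the PWM's consensus. This is the generative activity rule applied to
#' arbitrary sequences, e.g. designed candidates: at the default motif
#' sharpness, planted instances pass with high probability while the random
#' background rarely does.
#'
#' @param seq DNA string.
#' @param pwm Positions x 4 probability matrix.
#' @param max_mismatch Mismatches to the consensus tolerated per match.
#' @return Integer match count.
#' @export
motif_match_count <- function(seq, pwm, max_mismatch = 1L) {
  W <- nrow(pwm)
  consensus <- apply(pwm, 1, which.max)
  n_matches <- 0L
  for (s in c(seq, reverse_complement(seq))) {
    codes <- dna_codes(s)
    L <- length(codes)
    if (L < W) next
    mm <- integer(L - W + 1L)
    for (j in seq_len(W)) {
      cj <- codes[j:(L - W + j)]
      mm <- mm + (cj != consensus[j])  # N always mismatches
    }
    n_matches <- n_matches + sum(mm <= max_mismatch)
  }
  n_matches
}

#' Ground-truth activity of an arbitrary core sequence
#'
#' TRUE when the sequence contains at least the tissue's
#' \code{activity_rule} motif matches (see \code{\link{motif_match_count}}).
#'
#' @param seq DNA string (a 501-bp core, typically).
#' @param config \code{world_config}.
#' @param tissue Tissue name.
#' @param max_mismatch Match stringency passed to \code{motif_match_count}.
#' @return Logical.
#' @export
ground_truth_active <- function(seq, config, tissue, max_mismatch = 1L) {
  if (inherits(config, "synthetic_world")) config <- config$config
  motif_match_count(seq, config$motifs[[tissue]], max_mismatch) >=
    config$activity_rule[[tissue]]
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d chromosome(s) x %d bp, %d tissue(s)\n",
              x$config$n_chromosomes, x$config$chromosome_length,
              length(x$config$tissues)))
  cat(sprintf("  planted sites: %d | activity annotations: %d rows (%d active)\n",
              nrow(x$truth), nrow(x$activity),
              sum(x$activity$label == "active")))
  for (t in x$config$tissues)
    cat(sprintf("  %s: %d peak(s)\n", t, length(x$peaks[[t]])))
  invisible(x)
}

#' Write a synthetic world to standard file formats
#'
#' Emits \code{genome.fa}, one \code{<tissue>.bedGraph} and
#' \code{<tissue>.peaks.bed} per tissue, and \code{activity.tsv} (columns
#' chrom, start, end, stage_term, tissue_term, label; BED-style 0-based
#' half-open coordinates). Reading the files back reproduces the world up to
#' bedGraph precision; the planted-site truth is not exported.
#'
#' @param world A \code{synthetic_world}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
world_to_files <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$genome, file.path(dir, "genome.fa"))
  for (tissue in world$config$tissues) {
    write_bedgraph(world$tracks[[tissue]],
                   file.path(dir, paste0(tissue, ".bedGraph")))
    write_bed(world$peaks[[tissue]],
              file.path(dir, paste0(tissue, ".peaks.bed")))
  }
  act <- world$activity
  act$start <- act$start - 1L  # BED-style on disk
  utils::write.table(act, file.path(dir, "activity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a world directory written by \code{world_to_files}
#'
#' @param dir Directory containing genome.fa, per-tissue bedGraph/peaks.bed
#'   and activity.tsv.
#' @return List with genome, tracks, peaks and activity table (1-based
#'   coordinates in memory).
#' @export
read_world_files <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  lens <- genome_seqlengths(genome)
  bgs <- list.files(dir, pattern = "\\.bedGraph$")
  tissues <- sub("\\.bedGraph$", "", bgs)
  tracks <- lapply(tissues, function(t)
    read_bedgraph(file.path(dir, paste0(t, ".bedGraph")), lens))
  names(tracks) <- tissues
  peaks <- lapply(tissues, function(t)
    read_bed(file.path(dir, paste0(t, ".peaks.bed"))))
  names(peaks) <- tissues
  act <- utils::read.delim(file.path(dir, "activity.tsv"),
                           stringsAsFactors = FALSE)
  act$start <- act$start + 1L
  list(genome = genome, tracks = tracks, peaks = peaks, activity = act)
}
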
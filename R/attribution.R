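#' Dinucleotide-preserving sequence shuffle
#'
#' Generates shuffled sequences with exactly the same dinucleotide count
#' table as the input (hence also the same first and last base and the same
#' mononucleotide counts except possibly at the ends), sampled via the
#' Altschul-Erickson Euler-path construction: a random last-edge
#' arborescence towards the terminal base is drawn until it connects, the
#' remaining edges are permuted uniformly, and the Eulerian walk spells the
#' shuffle. Used to build attribution reference sequences.
#'
#' @param seq N-free DNA string of length >= 2.
#' @param n Number of shuffles.
#' @param seed Integer seed.
#' @return Character vector of n shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seq, n = 1L, seed = 1L) {
  codes <- dna_codes(seq)
  if (any(codes == 0)) stop("dinucleotide shuffle requires an N-free sequence")
  L <- length(codes)
  if (L < 2) stop("sequence must have length >= 2")
  local_seed(seed)
  bases <- c("A", "C", "G", "T")
  first <- codes[1]; last <- codes[L]
  # edge lists: successors of each base, in order of occurrence
  edges <- split(codes[-1], codes[-L])
  verts <- as.integer(names(edges))
  vapply(seq_len(n), function(i) {
    # draw last-out-edges forming paths into the terminal vertex
    repeat {
      last_edge <- stats::setNames(rep(NA_integer_, 4), bases)
      for (v in verts) {
        if (v == last) next
        es <- edges[[as.character(v)]]
        last_edge[v] <- es[[sample.int(length(es), 1)]]
      }
      ok <- TRUE
      for (v in verts) {
        if (v == last) next
        cur <- v; hops <- 0L
        while (cur != last) {
          cur <- last_edge[cur]
          hops <- hops + 1L
          if (is.na(cur) || hops > 4L) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute remaining edges; the chosen last edge is used last
    walk_edges <- lapply(stats::setNames(as.character(verts), verts),
      function(vn) {
        v <- as.integer(vn)
        es <- edges[[vn]]
        if (v != last) {
          drop_i <- match(last_edge[v], es)
          rest <- es[-drop_i]
          c(if (length(rest) > 1) rest[sample.int(length(rest))] else rest,
            last_edge[v])
        } else if (length(es) > 1) es[sample.int(length(es))] else es
      })
    used <- stats::setNames(rep(0L, length(walk_edges)), names(walk_edges))
    out <- integer(L)
    out[1] <- first
    cur <- first
    for (p in 2:L) {
      vn <- as.character(cur)
      used[vn] <- used[vn] + 1L
      cur <- walk_edges[[vn]][used[vn]]
      out[p] <- cur
    }
    paste(bases[out], collapse = "")
  }, character(1))
}

#' Dinucleotide count table of a sequence
#'
#' @param seq DNA string.
#' @return 4 x 4 matrix of counts, rows = first base, cols = second.
#' @export
dinucleotide_counts <- function(seq) {
  codes <- dna_codes(seq)
  if (any(codes == 0)) stop("N-free sequence required")
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  if (length(codes) >= 2) {
    tab <- table(factor(codes[-length(codes)], levels = 1:4),
                 factor(codes[-1], levels = 1:4))
    m[] <- as.integer(tab)
  }
  m
}

#' Multi-reference integrated gradients on one-hot sequence input
#'
#' Path-integrated gradients from each reference to the input, averaged
#' over references. Per reference, the average path gradient M (4 x L over
#' \code{steps} midpoint evaluations) is projected into hypothetical scores
#' \code{M[b,l] - sum_b' ref[b',l] M[b',l]} (the contribution each possible
#' base would receive relative to the reference at that position); actual
#' scores are the hypothetical scores at the observed bases. The actual
#' scores satisfy the completeness identity: their sum approximates
#' \code{f(x) - mean_ref f(ref)}, exactly so for linear \code{f}.
#'
#' @param f Function: dense 4 x (L*B) one-hot-like matrix -> numeric vector
#'   of B scores.
#' @param grad_f Function: dense 4 x (L*B) matrix -> 4 x (L*B) gradient.
#' @param x One-hot input, 4 x L matrix.
#' @param refs List of reference matrices (4 x L each).
#' @param steps Number of path integration steps (default 64).
#' @return List: hypothetical (L x 4), actual (L x 4), f_x, f_ref_mean,
#'   completeness_error (relative).
#' @export
integrated_gradients <- function(f, grad_f, x, refs, steps = 64L) {
  L <- ncol(x)
  hyp_sum <- matrix(0, 4, L)
  f_x <- f(x)[1]
  f_refs <- numeric(length(refs))
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    alphas <- (seq_len(steps) - 0.5) / steps
    path <- matrix(0, 4, L * steps)
    diffmat <- x - r
    for (t in seq_len(steps)) {
      path[, ((t - 1) * L + 1):(t * L)] <- r + alphas[t] * diffmat
    }
    g <- grad_f(path)
    M <- matrix(0, 4, L)
    for (t in seq_len(steps)) {
      M <- M + g[, ((t - 1) * L + 1):(t * L)]
    }
    M <- M / steps
    proj <- colSums(r * M)  # reference expectation per position
    hyp_sum <- hyp_sum + sweep(M, 2, proj, "-")
    f_refs[i] <- f(r)[1]
  }
  hyp <- hyp_sum / length(refs)
  actual <- hyp * x
  delta <- f_x - mean(f_refs)
  comp_err <- if (abs(delta) > 0) abs(sum(actual) - delta) / abs(delta) else
    abs(sum(actual))
  list(hypothetical = t(hyp), actual = t(actual), f_x = f_x,
       f_ref_mean = mean(f_refs), completeness_error = comp_err)
}

#' Nucleotide contribution scores for a sequence under a model
#'
#' Computes per-position, per-base attribution maps for a trained model
#' against dinucleotide-shuffled reference sequences (default 100),
#' via multi-reference integrated gradients on the model's pre-activation
#' output (the logit, for sigmoid heads). Hypothetical scores give the
#' attribution every possible base would receive at each position; actual
#' scores are the hypothetical scores multiplied by the one-hot encoded
#' sequence.
#'
#' @param model Trained \code{cnn_model}.
#' @param seq N-free DNA string of the model's input length.
#' @param n_refs Number of dinucleotide-shuffled references (default 100).
#' @param steps Integration steps per reference (default 64).
#' @param seed Seed for the reference shuffles.
#' @return Object of class \code{contribution_map}: sequence, hypothetical
#'   and actual L x 4 score matrices, model output, reference mean and the
#'   relative completeness error.
#' @export
contribution_scores <- function(model, seq, n_refs = 100L, steps = 64L,
                                seed = 1L) {
  stopifnot(inherits(model, "cnn_model"))
  if (!isTRUE(model$meta$trained))
    stop("contribution scores require a trained model")
  seq <- toupper(seq)
  if (nchar(seq) != model$spec$input_length)
    stop("sequence length does not match model input length")
  x <- t(one_hot_encode(seq))  # 4 x L
  ref_seqs <- dinucleotide_shuffle(seq, n = n_refs, seed = seed)
  refs <- lapply(ref_seqs, function(s) t(one_hot_encode(s)))
  arch <- .arch_for_cpp(model)
  f <- function(X) cpp_cnn_predict_dense(model$params, arch, X, raw = TRUE)
  grad_f <- function(X) cpp_cnn_input_grad(model$params, arch, X)
  ig <- integrated_gradients(f, grad_f, x, refs, steps = steps)
  structure(list(seq = seq, hypothetical = ig$hypothetical,
                 actual = ig$actual, f_x = ig$f_x,
                 f_ref_mean = ig$f_ref_mean,
                 completeness_error = ig$completeness_error,
                 n_refs = n_refs, steps = steps),
            class = "contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf("Contribution map over %d bp (%d refs, %d steps)\n",
              nchar(x$seq), x$n_refs, x$steps))
  cat(sprintf("  f(x) = %.4g, mean f(ref) = %.4g, completeness error %.3g\n",
              x$f_x, x$f_ref_mean, x$completeness_error))
  invisible(x)
}

#' Average contribution maps across cross-validation folds
#'
#' Elementwise mean of the hypothetical and actual score matrices of maps
#' computed for the same sequence under different fold models.
#'
#' @param maps List of \code{contribution_map}s with identical sequence.
#' @return A \code{contribution_map} with averaged scores.
#' @export
average_contributions <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(dim(m$actual), dim(ref$actual)) ||
        !identical(m$seq, ref$seq))
      stop("contribution maps must share one sequence and shape")
  }
  out <- ref
  out$hypothetical <- Reduce(`+`, lapply(maps, `[[`, "hypothetical")) / length(maps)
  out$actual <- Reduce(`+`, lapply(maps, `[[`, "actual")) / length(maps)
  out$f_x <- mean(vapply(maps, `[[`, numeric(1), "f_x"))
  out$f_ref_mean <- mean(vapply(maps, `[[`, numeric(1), "f_ref_mean"))
  out$completeness_error <- NA_real_
  out
}

#' Per-position information content of a PWM
#'
#' Bits against a uniform background: IC = 2 + sum_b p_b log2 p_b.
#'
#' @param pwm Positions x 4 probability matrix.
#' @return Numeric vector of per-position IC in [0, 2].
#' @export
pwm_ic <- function(pwm) {
  stopifnot(is.matrix(pwm), ncol(pwm) == 4)
  apply(pwm, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Trim low-information flanks from a PWM
#'
#' Removes leading and trailing positions with information content below
#' the threshold; interior low-IC positions are retained. A fully trimmed
#' (empty) result is flagged via \code{attr(, "empty")}.
#'
#' @param pwm Positions x 4 probability matrix.
#' @param ic_threshold Minimum flank IC in bits (default 0.4).
#' @return The trimmed PWM (possibly with zero rows).
#' @export
trim_pwm <- function(pwm, ic_threshold = 0.4) {
  ic <- pwm_ic(pwm)
  keep <- ic >= ic_threshold
  if (!any(keep)) {
    out <- pwm[integer(0), , drop = FALSE]
    attr(out, "empty") <- TRUE
    return(out)
  }
  lo <- min(which(keep)); hi <- max(which(keep))
  out <- pwm[lo:hi, , drop = FALSE]
  attr(out, "empty") <- FALSE
  out
}

#' Write PWMs in MEME minimal text format
#'
#' @param pwms Named list of positions x 4 probability matrices.
#' @param path Output path.
#' @param background Background base frequencies.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6g C %.6g G %.6g T %.6g", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", nrow(m)),
               con)
    for (i in seq_len(nrow(m)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m[i, 1], m[i, 2], m[i, 3],
                         m[i, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal text format
#'
#' @param path MEME file.
#' @return Named list of positions x 4 probability matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !startsWith(lines[j], "letter-probability matrix")) j <- j + 1L
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[j]))
      rows <- lapply(lines[(j + 1):(j + w)], function(ln)
        as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      m <- do.call(rbind, rows)
      colnames(m) <- c("A", "C", "G", "T")
      out[[nm]] <- m
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}
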
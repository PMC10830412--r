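#' @useDynLib enforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a multi-record FASTA file into a genome assembly
#'
#' A genome assembly is represented as a named character vector of chromosome
#' sequences over the alphabet A, C, G, T, N. Sequences are case-normalized to
#' upper case on load and validated; chromosome names must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) .fasta_format_error(path, conditionMessage(e))
  )
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  # header lines may carry descriptions after the identifier
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate chromosome name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty name in ", path)
  if (any(nchar(seqs) < 1L)) {
    stop("FASTA record(s) with empty sequence: ",
         paste(names(seqs)[nchar(seqs) < 1L], collapse = ", "))
  }
  bad <- vapply(seqs, function(s) {
    grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), s)
  }, logical(1))
  if (any(bad)) .fasta_alphabet_error(path, seqs, names(seqs)[bad][1])
  validate_genome(seqs)
}

# locate the first offending line for a useful format error
.fasta_alphabet_error <- function(path, seqs, record) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    if (grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), toupper(ln))) {
      stop(sprintf(
        "invalid sequence character(s) at line %d of %s (record '%s'); allowed: %s",
        i, path, record, paste(DNA_ALPHABET, collapse = "")))
    }
  }
  stop("invalid sequence character(s) in record '", record, "' of ", path)
}

.fasta_format_error <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(lines[first], ">")) {
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header", first, path))
  }
  stop("malformed FASTA file ", path, ": ", msg)
}

#' Validate a genome assembly object
#'
#' @param genome Named character vector of chromosome sequences.
#' @return The validated genome (invisibly usable in pipelines).
#' @export
validate_genome <- function(genome) {
  stopifnot(is.character(genome), length(genome) >= 1)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome chromosomes must be named")
  if (anyDuplicated(names(genome))) stop("chromosome names must be unique")
  if (any(nchar(genome) < 1L)) stop("chromosome lengths must be >= 1")
  genome
}

#' Write a genome assembly to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome assembly
#' @param genome Named character vector of sequences.
#' @return Named integer vector of lengths.
#' @export
genome_seqlengths <- function(genome) {
  validate_genome(genome)
  stats::setNames(nchar(genome), names(genome))
}

.check_dna <- function(seq) {
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         substr(seq[bad][1], 1, 40))
  }
  invisible(seq)
}

#' One-hot encode a DNA sequence
#'
#' Encodes a DNA string as an L x 4 indicator matrix with column order
#' A, C, G, T: A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1).
#' N encodes as an all-zero row, so row sums are 1 for determinate bases and
#' 0 for N.
#'
#' @param seq A single DNA string over {A,C,G,T,N} (case-insensitive).
#' @return Numeric matrix of dimension nchar(seq) x 4 with colnames ACGT.
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  .check_dna(seq)
  codes <- dna_codes(seq)
  L <- length(codes)
  m <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- codes > 0L
  if (any(keep)) m[cbind(which(keep), codes[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' All-zero rows decode to N.
#'
#' @param mat L x 4 one-hot matrix (columns A,C,G,T).
#' @return DNA string.
#' @export
one_hot_decode <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4)
  if (nrow(mat) == 0) return("")
  hits <- max.col(mat, ties.method = "first")
  hits[rowSums(mat) == 0] <- 5L
  paste(DNA_ALPHABET[hits], collapse = "")
}

#' Integer base codes for a DNA string (A=1, C=2, G=3, T=4, N=0)
#'
#' Internal encoding shared with the compiled network code.
#'
#' @param seq DNA string.
#' @return Integer vector of length nchar(seq).
#' @export
dna_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick complement with N mapping to N; an involution.
#'
#' @param seq Character vector of DNA strings over {A,C,G,T,N}.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  seq <- toupper(seq)
  .check_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Read a BED3+ interval file
#'
#' Returns intervals as a GRanges in file order. BED's 0-based half-open
#' coordinates are converted to the 1-based closed GRanges convention at the
#' boundary. Chromosome names unknown to any particular genome are permitted
#' at read time and validated where the intervals are used.
#'
#' @param path BED file path.
#' @return GRanges.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  n <- length(readLines(path, warn = FALSE))
  if (n == 0) return(GenomicRanges::GRanges())
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e))
  )
  if (any(GenomicRanges::width(gr) < 1L)) {
    i <- which(GenomicRanges::width(gr) < 1L)[1]
    stop(sprintf("malformed BED interval (start >= end) at record %d of %s", i, path))
  }
  gr
}

#' Write intervals as 3-column BED
#'
#' @param gr GRanges.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a dense per-base track
#'
#' A coverage track is a named list with one non-negative numeric vector per
#' chromosome, one value per base. Positions absent from the bedGraph fill
#' with 0.
#'
#' @param path bedGraph file.
#' @param seqlengths Named integer vector of chromosome lengths (for the dense
#'   representation).
#' @return Named list of numeric vectors.
#' @export
read_bedgraph <- function(path, seqlengths) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- lapply(names(seqlengths), function(chrom) numeric(seqlengths[[chrom]]))
  names(track) <- names(seqlengths)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% names(seqlengths)]
  chroms <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  scores <- S4Vectors::mcols(gr)$score
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    v <- track[[chrom]]
    for (i in idx) {
      e <- min(ends[i], length(v))
      if (starts[i] <= e) v[starts[i]:e] <- scores[i]
    }
    track[[chrom]] <- v
  }
  validate_track(track, seqlengths)
}

#' Validate a dense coverage track against chromosome lengths
#' @param track Named list of numeric vectors.
#' @param seqlengths Named lengths the track must match.
#' @return The track.
#' @export
validate_track <- function(track, seqlengths = NULL) {
  stopifnot(is.list(track), !is.null(names(track)))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    if (!is.numeric(v)) stop("track values must be numeric: ", chrom)
    if (any(!is.finite(v))) stop("track contains non-finite values: ", chrom)
    if (any(v < 0)) stop("track contains negative values: ", chrom)
    if (!is.null(seqlengths) && length(v) != seqlengths[[chrom]])
      stop(sprintf("track length %d != chromosome length %d for %s",
                   length(v), seqlengths[[chrom]], chrom))
  }
  track
}

#' Write a dense coverage track as bedGraph
#'
#' Adjacent equal values are run-length compressed; values are written with
#' six significant digits.
#'
#' @param track Named list of numeric per-base vectors.
#' @param path Output path.
#' @param digits Significant digits to keep.
#' @export
write_bedgraph <- function(track, path, digits = 6L) {
  validate_track(track)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- S4Vectors::Rle(signif(track[[chrom]], digits))
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based starts
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom, starts[keep], ends[keep],
                       vals[keep]), con)
  }
  invisible(path)
}

#' Extract sequences for intervals from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gr GRanges within the genome.
#' @return Character vector of sequences, one per range.
#' @export
interval_sequences <- function(genome, gr) {
  validate_genome(genome)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lens <- genome_seqlengths(genome)
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > lens[chroms]))
    stop("interval(s) outside chromosome bounds")
  unname(substring(genome[chroms], GenomicRanges::start(gr),
                   GenomicRanges::end(gr)))
}
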
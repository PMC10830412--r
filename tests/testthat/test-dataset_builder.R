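test_that("tiling matches brute-force enumeration", {
  # stated examples
  g <- c(chr1 = paste(rep("A", 1101), collapse = ""))
  t1 <- tile_genome(g)
  expect_equal(GenomicRanges::start(t1), c(1L, 51L, 101L))
  expect_length(tile_genome(c(c1 = strrep("A", 1000))), 0)
  expect_length(tile_genome(c(c1 = strrep("A", 1001))), 1)

  # property: count formula equals brute force for random (L, stride)
  set.seed(42)
  for (i in 1:25) {
    L <- sample(500:3000, 1); w <- sample(50:600, 1); s <- sample(1:200, 1)
    got <- length(tile_genome(stats::setNames(strrep("A", L), "c"), w, s))
    brute <- 0L; pos <- 1L
    while (pos + w - 1L <= L) { brute <- brute + 1L; pos <- pos + s }
    expect_equal(got, brute, info = sprintf("L=%d w=%d s=%d", L, w, s))
  }
})

test_that("window signal is the log mean over the central 201 bp", {
  L <- 1500L
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, width = 1001))
  # constant coverage 1.0, zero pseudocount -> natural log of 1
  expect_equal(window_signal(list(chr1 = rep(1, L)), gr, pseudocount = 0), 0)
  # all-zero coverage with pseudocount
  expect_equal(window_signal(list(chr1 = numeric(L)), gr, pseudocount = 1e-3),
               log(1e-3))
  # coverage = position index: brute-force central mean oracle
  track <- list(chr1 = as.numeric(seq_len(L)))
  s0 <- 100L  # 1-based window start
  central <- (s0 + 400):(s0 + 600)
  expect_length(central, 201)
  expect_equal(window_central_mean(track, gr), mean(track$chr1[central]))
  expect_equal(window_signal(track, gr), log(mean(track$chr1[central]) + 1e-3))
  # out-of-bounds error
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(L - 500, width = 1001))
  expect_error(window_central_mean(track, far), "outside")
})

test_that("peak-anchored selection follows the central-151-in-301 rule", {
  set.seed(7)
  g <- c(chr1 = random_dna(1, 30000))
  tiles <- tile_genome(g)
  track <- list(chr1 = runif(30000, 0.5, 2))
  tr <- list(t1 = track)
  # background peaks exactly covering the central region of every 10th tile
  # (301 bp at the tile midpoint: recentering is the identity)
  bg_starts <- GenomicRanges::start(tiles)[seq(11, length(tiles), by = 10)]
  bg_peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(bg_starts + 350L, width = 301L))
  # probe peak: wide, recentres to 351..651 which contains the central
  # 151 bp (426..576) of the tile starting at 1
  probe_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 701))
  ds <- select_training_windows(tiles, c(bg_peaks, probe_in), tr, g,
                                n_random = 0)
  expect_true(1L %in% ds$windows$start)
  # probe overlapping the central region by only ~100 bases fails the rule:
  # recentred to 301 around midpoint 676 -> 526..826, central 151 not within
  probe_out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(526, 826))
  ds2 <- select_training_windows(tiles, c(bg_peaks, probe_out), tr, g,
                                 n_random = 0)
  expect_false(1L %in% ds2$windows$start)
  # every selected window really satisfies the containment rule
  rec <- c(bg_peaks, probe_in)
  mids <- (GenomicRanges::start(rec) + GenomicRanges::end(rec)) %/% 2L
  rec301 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(mids - 150L, width = 301L))
  for (s0 in ds$windows$start) {
    c151 <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(s0 + 425L, width = 151L))
    expect_true(any(GenomicRanges::countOverlaps(c151, rec301,
                                                 type = "within") > 0))
  }
})

test_that("quantile filter matches an independent sort-based oracle", {
  set.seed(19)
  n <- 1000L
  g <- c(chr1 = random_dna(1, 1001 + 50 * (n - 1)))
  tiles <- tile_genome(g)[seq_len(n)]
  # continuous coverage with one extreme window
  v <- runif(nchar(g), 1, 2)
  v[(500 * 50 + 401):(500 * 50 + 601)] <- 5000  # blow up window 501's centre
  track <- list(t1 = list(chr1 = v))
  # one 301-bp peak at every tile midpoint: recentering is the identity and
  # every tile passes the containment rule
  all_peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(GenomicRanges::start(tiles) + 350L, width = 301L))
  ds <- select_training_windows(tiles, all_peaks, track, g, n_random = 0)
  expect_false(25001L %in% ds$windows$start)  # extreme window removed

  # oracle: recompute targets and apply the quantile rule by sorting
  mu <- window_central_mean(track$t1, tiles)
  y <- log(mu + 1e-3)
  q <- stats::quantile(y, c(0.01, 0.999), names = FALSE)
  keep <- mu > 0 & y >= q[1] & y <= q[2]
  expect_equal(nrow(ds$windows), sum(keep))
  expect_equal(ds$windows$start, GenomicRanges::start(tiles)[keep])
})

test_that("reverse-complement augmentation doubles once and only once", {
  set.seed(3)
  g <- c(chr1 = random_dna(1, 3200))
  tiles <- tile_genome(g)
  track <- list(t1 = list(chr1 = runif(3200, 0.5, 2)))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3200))
  ds <- select_training_windows(tiles, peaks, track, g, n_random = 0)
  n0 <- nrow(ds$windows)
  expect_gt(n0, 0)
  aug <- augment_reverse_complement(ds)
  expect_equal(nrow(aug$windows), 2L * n0)
  # partner: reverse-complemented sequence, identical target
  expect_identical(aug$seq[n0 + 1], reverse_complement(ds$seq[1]))
  expect_equal(aug$targets[n0 + 1, ], ds$targets[1, ])
  expect_identical(aug$windows$strand, rep(c("+", "-"), each = n0))
  expect_error(augment_reverse_complement(aug), "already")
})

test_that("chromosome-half fold plan satisfies the rotation invariants", {
  set.seed(1)
  g <- stats::setNames(random_dna(5, 4000), paste0("chr", 1:5))
  plan <- fold_plan(g, n_folds = 10, seed = 2)
  # 5 chromosomes -> 10 halves -> one half per fold
  expect_equal(nrow(plan$halves), 10)
  expect_setequal(plan$halves$fold, 1:10)
  # rotations: every fold exactly once as test; val != test
  expect_setequal(plan$rotations$test, 1:10)
  expect_true(all(plan$rotations$val != plan$rotations$test))

  # windows: union of folds = all, pairwise disjoint by construction,
  # each window in exactly one test fold across the rotations
  tiles <- tile_genome(g, 501, 100)
  f <- fold_of_intervals(plan, as.character(GenomicRanges::seqnames(tiles)),
                         GenomicRanges::start(tiles),
                         GenomicRanges::end(tiles))
  expect_true(all(f %in% 1:10))
  test_hits <- vapply(1:10, function(k) sum(f == k), integer(1))
  expect_equal(sum(test_hits), length(tiles))

  # boundary tie-break: midpoint exactly at the split goes left
  h <- nchar(g[["chr1"]]) %/% 2L
  left_fold <- plan$halves$fold[plan$halves$chrom == "chr1" &
                                plan$halves$start == 1L]
  expect_equal(fold_of_intervals(plan, "chr1", h - 10L, h + 10L), left_fold)
})

test_that("folds require enough chromosome halves and are inherited by pairs", {
  g2 <- stats::setNames(random_dna(2, 3000), c("chrA", "chrB"))
  expect_error(fold_plan(g2, n_folds = 10), "halves")
  plan <- fold_plan(g2, n_folds = 4, seed = 1)
  tiles <- tile_genome(g2, 501, 250)
  track <- list(t1 = lapply(g2, function(s) runif(nchar(s), 0.5, 2)))
  peaks <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 3000))
  ds <- select_training_windows(tile_genome(g2), peaks, track, g2,
                                n_random = 0)
  ds <- assign_folds(ds, plan)
  aug <- augment_reverse_complement(ds)
  n0 <- nrow(ds$windows)
  expect_identical(aug$fold[seq_len(n0)], aug$fold[n0 + seq_len(n0)])
})
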
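mk_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), stage_term = r[[4]],
               tissue_term = r[[5]], label = r[[6]],
               stringsAsFactors = FALSE)))
}

# term map mirroring the brain-vs-CNS structure: brain terms are a subset of
# CNS terms but brain additionally excludes ventral-nerve-cord activity
nervous_map <- list(
  cns = list(terms = c("ventral nerve cord", "embryonic brain"),
             exclude_terms = character(0)),
  brain = list(terms = "embryonic brain",
               exclude_terms = "ventral nerve cord"))

test_that("stage terms parse to ranges", {
  m <- parse_stage_term(c("stage13-16", "stage11", "weird"))
  expect_equal(m[1, ], c(13L, 16L))
  expect_equal(m[2, ], c(11L, 11L))
  expect_true(all(is.na(m[3, ])))
})

test_that("labeling follows term lists, stages, and the exclusion rule", {
  r1 <- mk_records(list("c1", 1, 2001, "stage13-16", "embryonic brain", "active"))
  l1 <- label_records(r1, nervous_map)
  expect_true(l1$brain)
  expect_true(l1$cns)

  # active in brain terms AND the VNC -> brain inactive, CNS active
  r2 <- mk_records(
    list("c1", 1, 2001, "stage13-16", "embryonic brain", "active"),
    list("c1", 1, 2001, "stage14", "ventral nerve cord", "active"))
  l2 <- label_records(r2, nervous_map)
  expect_false(l2$brain)
  expect_true(l2$cns)

  # activity outside stages 13-16 does not count
  r3 <- mk_records(list("c1", 1, 2001, "stage11", "embryonic brain", "active"))
  l3 <- label_records(r3, nervous_map)
  expect_false(l3$brain)
  expect_false(l3$cns)

  # unknown terms warn and are ignored
  r4 <- mk_records(list("c1", 1, 2001, "stage13-16", "mystery tissue", "active"))
  expect_warning(l4 <- label_records(r4, nervous_map), "unknown")
  expect_false(l4$cns)
})

test_that("labeling is monotone in added evidence except via exclusions", {
  set.seed(21)
  terms <- c("ventral nerve cord", "embryonic brain")
  for (i in 1:20) {
    n <- sample(1:4, 1)
    base <- do.call(mk_records, lapply(seq_len(n), function(j)
      list("c1", 1, 2001, sample(c("stage13-16", "stage4-6"), 1),
           sample(terms, 1), sample(c("active", "inactive"), 1))))
    extra <- mk_records(list("c1", 1, 2001, "stage13-16", "embryonic brain",
                             "active"))
    l0 <- label_records(base, nervous_map)
    l1 <- label_records(rbind(base, extra), nervous_map)
    # cns (no exclusions) can only gain activity
    expect_true(l1$cns >= l0$cns)
    # brain can flip off only through the VNC exclusion, never through an
    # added brain-term record
    if (l0$brain) expect_true(l1$brain)
  }
  # and a VNC record CAN flip brain off
  on <- mk_records(list("c1", 1, 2001, "stage13-16", "embryonic brain", "active"))
  off <- rbind(on, mk_records(list("c1", 1, 2001, "stage13-16",
                                   "ventral nerve cord", "active")))
  expect_true(label_records(on, nervous_map)$brain)
  expect_false(label_records(off, nervous_map)$brain)
})

test_that("activity dataset construction follows the overlap and sampling rules", {
  set.seed(6)
  g <- c(cA = random_dna(1, 12000), cB = random_dna(1, 12000))
  plan <- fold_plan(g, n_folds = 4, seed = 1)
  # fragments: two active, one inactive (long enough for 5+ tiles)
  labels <- data.frame(chrom = c("cA", "cA", "cB"),
                       start = c(1L, 4001L, 1L),
                       end = c(3501L, 7501L, 4501L),
                       t1 = c(TRUE, TRUE, FALSE))
  # peak overlapping tiles of fragment 1 only
  peaks <- GenomicRanges::GRanges("cA", IRanges::IRanges(1, 2000))
  ds <- build_activity_dataset(labels, "t1", g, peaks, plan, seed = 2,
                               tile_stride = 500L)
  n0 <- nrow(ds$windows) / 2  # pre-augmentation
  pos <- ds$windows[ds$windows$origin == "positive" &
                    ds$windows$strand == "+", ]
  # brute-force oracle: tiles of active fragments with >= 151 bp overlap
  brute <- 0L
  for (i in which(labels$t1)) {
    starts <- seq(labels$start[i], labels$end[i] - 1000L, by = 500L)
    for (s in starts) {
      ov <- min(s + 1000L, 2000L) - max(s, 1L) + 1L
      if (labels$chrom[i] == "cA" && ov >= 151L) brute <- brute + 1L
    }
  }
  expect_equal(nrow(pos), brute)
  # negatives: at most 5 per fragment (fragment 3 tiles: length 4501 -> 8)
  neg <- ds$windows[ds$windows$origin == "negative" &
                    ds$windows$strand == "+", ]
  expect_lte(nrow(neg), 5L)
  # folds inherited from the chromosome-half plan
  expect_equal(ds$fold,
               fold_of_intervals(plan, ds$windows$chrom, ds$windows$start,
                                 ds$windows$end))
  # augmentation doubled
  expect_equal(nrow(ds$windows), 2 * n0)
  # boundary: a peak overlapping by exactly 150 bp yields no positives
  peaks150 <- GenomicRanges::GRanges("cA", IRanges::IRanges(852, 1001))
  labels2 <- labels[labels$chrom == "cA" & labels$start == 1L, , drop = FALSE]
  expect_error(build_activity_dataset(labels2, "t1", g, peaks150, plan,
                                      tile_stride = 2000L), "zero positive")
})

test_that("negative down-sampling is seeded and never drops positives", {
  set.seed(6)
  g <- c(cA = random_dna(1, 12000), cB = random_dna(1, 12000))
  plan <- fold_plan(g, n_folds = 4, seed = 1)
  labels <- data.frame(chrom = c("cA", "cB"), start = c(1L, 1L),
                       end = c(3501L, 6001L), t1 = c(TRUE, FALSE))
  peaks <- GenomicRanges::GRanges("cA", IRanges::IRanges(1, 3500))
  d1 <- build_activity_dataset(labels, "t1", g, peaks, plan, seed = 9)
  d2 <- build_activity_dataset(labels, "t1", g, peaks, plan, seed = 9)
  expect_identical(d1$windows, d2$windows)
  n_pos_all <- sum(GenomicRanges::countOverlaps(
    GenomicRanges::GRanges("cA", IRanges::IRanges(seq(1, 2501, 500),
                                                  width = 1001)),
    peaks, minoverlap = 151) > 0)
  expect_equal(sum(d1$windows$origin == "positive"), 2 * n_pos_all)
})

test_that("transfer initialization copies the body and replaces the head", {
  src <- tiny_trained_model()
  clf <- transfer_init(src, seed = 21)
  expect_identical(clf$spec$head, "sigmoid")
  expect_identical(clf$params$conv, src$params$conv)
  expect_identical(clf$params$dense, src$params$dense)
  expect_false(identical(clf$params$head, src$params$head))
  clf2 <- transfer_init(src, seed = 22)
  expect_false(identical(clf$params$head$W, clf2$params$head$W))
  expect_identical(clf$params$conv, clf2$params$conv)
  # sigmoid outputs in (0, 1)
  p <- predict(clf, random_dna(5, 81, seed = 3))
  expect_true(all(p > 0 & p < 1))
  # untrained or classification sources are rejected
  expect_error(transfer_init(build_model(tiny_spec(), 1)), "trained")
})

test_that("fine-tuning beats or matches random init on a small toy task", {
  src <- tiny_trained_model()
  # toy activity task reusing the same motif: ~60 labeled originals
  task <- toy_motif_task(n = 120, seed = 31, binary = TRUE)
  g <- stats::setNames(random_dna(4, 2000, seed = 40), paste0("chr", 1:4))
  plan <- fold_plan(g, n_folds = 4, seed = 1)
  # hand-build an activity-dataset-shaped object on the toy sequences
  folds <- rep(1:4, length.out = 120)
  ds <- enforge:::new_regression_dataset(
    windows = data.frame(chrom = "chr1", start = 1L, end = 81L, strand = "+",
                         origin = ifelse(task$lab == 1, "positive", "negative"),
                         source_id = seq_len(120)),
    seq = task$seqs,
    targets = matrix(task$lab, ncol = 1, dimnames = list(NULL, "label")),
    fold = folds)
  ds$fold_plan <- plan
  ds <- augment_reverse_complement(ds)
  class(ds) <- c("activity_dataset", class(ds))

  cfg <- train_config(learning_rate = 1e-4, loss = "bce", patience = 20,
                      max_epochs = 25, seed = 1)
  cmp <- compare_initializations(ds, test_fold = 1, source = src,
                                 seeds = 1:2, config = cfg)
  expect_setequal(unique(cmp$mode), c("transfer", "random_init"))
  agg <- tapply(cmp$auprc, cmp$mode, mean)
  expect_gte(agg[["transfer"]] + 0.05, agg[["random_init"]])
})

test_that("off-tissue baseline copies donor weights and selects by name on ties", {
  src <- tiny_trained_model()
  task <- toy_motif_task(n = 60, seed = 33, binary = TRUE)
  plan <- fold_plan(stats::setNames(random_dna(4, 2000, seed = 41),
                                    paste0("chr", 1:4)), n_folds = 4, seed = 1)
  ds <- enforge:::new_regression_dataset(
    windows = data.frame(chrom = "chr1", start = 1L, end = 81L, strand = "+",
                         origin = "x", source_id = seq_len(60)),
    seq = task$seqs,
    targets = matrix(task$lab, ncol = 1, dimnames = list(NULL, "label")),
    fold = rep(1:4, length.out = 60))
  ds$fold_plan <- plan
  ds <- augment_reverse_complement(ds)
  cfg <- train_config(learning_rate = 1e-4, loss = "bce", patience = 3,
                      max_epochs = 3, seed = 1)
  out <- baseline_train("off_tissue", ds, test_fold = 1,
                        donors = list(saliva = src), config = cfg, seed = 2)
  expect_identical(out$meta$donor, "saliva")
  expect_error(baseline_train("off_tissue", ds, 1, donors = NULL,
                              config = cfg), "donor")
  # random init differs from the donor's body
  rnd <- baseline_train("random_init", ds, test_fold = 1, config = cfg,
                        seed = 2, spec = tiny_spec(head = "sigmoid"))
  expect_false(identical(rnd$params$conv[[1]]$W, src$params$conv[[1]]$W))
})
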
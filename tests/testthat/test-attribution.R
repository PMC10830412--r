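test_that("dinucleotide shuffles preserve the dinucleotide count table", {
  expect_identical(dinucleotide_shuffle("AAAA", n = 3, seed = 1),
                   rep("AAAA", 3))
  # ACAC admits a single Eulerian arrangement
  expect_identical(unique(dinucleotide_shuffle("ACAC", n = 10, seed = 2)),
                   "ACAC")
  set.seed(10)
  for (i in 1:300) {
    s <- random_dna(1, 50)
    sh <- dinucleotide_shuffle(s, n = 1, seed = i)
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, 50, 50), substr(s, 50, 50))
  }
  # seeded reproducibility, and shuffles differ from the input in general
  s <- random_dna(1, 200, seed = 3)
  a <- dinucleotide_shuffle(s, n = 5, seed = 9)
  b <- dinucleotide_shuffle(s, n = 5, seed = 9)
  expect_identical(a, b)
  expect_gt(length(unique(a)), 1)
  expect_error(dinucleotide_shuffle("ANA"), "N-free")
  expect_error(dinucleotide_shuffle("A"), "length")
})

# linear scorer closures over the dense 4 x (L*B) representation:
# f(x) = sum(W * x) + c per sample
linear_f <- function(W, const = 0) {
  L <- ncol(W)
  function(X) {
    B <- ncol(X) / L
    vapply(seq_len(B), function(s)
      sum(W * X[, ((s - 1) * L + 1):(s * L)]) + const, numeric(1))
  }
}
linear_grad <- function(W) {
  L <- ncol(W)
  function(X) {
    B <- ncol(X) / L
    do.call(cbind, rep(list(W), B))
  }
}

test_that("integrated gradients are exact for linear models", {
  set.seed(12)
  L <- 30
  W <- matrix(rnorm(4 * L), 4, L)
  s <- random_dna(1, L)
  x <- t(one_hot_encode(s))
  refs <- lapply(dinucleotide_shuffle(s, n = 7, seed = 5),
                 function(r) t(one_hot_encode(r)))
  f <- linear_f(W, const = 0.3)
  ig <- integrated_gradients(f, linear_grad(W), x, refs, steps = 4)
  # completeness is exact for a linear function
  expect_equal(sum(ig$actual), ig$f_x - ig$f_ref_mean, tolerance = 1e-10)
  expect_lt(ig$completeness_error, 1e-10)
  # actual scores equal the weight of the observed base minus the
  # reference-average weight at that position
  rbar <- Reduce(`+`, refs) / length(refs)
  expected_actual <- t((W - matrix(colSums(rbar * W), 4, L, byrow = TRUE)) * x)
  expect_equal(ig$actual, expected_actual, tolerance = 1e-10)
  # hypothetical x one-hot reproduces the actual scores
  expect_equal(ig$actual, ig$hypothetical * one_hot_encode(s))
  # constant f attributes nothing
  ig0 <- integrated_gradients(function(X) rep(2, ncol(X) / L),
                              function(X) matrix(0, 4, ncol(X)), x, refs,
                              steps = 2)
  expect_true(all(ig0$actual == 0))
})

test_that("attribution is reverse-complement equivariant for a
           strand-symmetrized linear scorer", {
  set.seed(13)
  L <- 24
  W <- matrix(rnorm(4 * L), 4, L)
  # symmetrize: g(x) = f(x) + f(rc(x)); on one-hot matrices rc is
  # row/column reversal
  rc_mat <- function(X) X[4:1, rev(seq_len(ncol(X))), drop = FALSE]
  f1 <- linear_f(W)
  f <- function(X) {
    B <- ncol(X) / L
    out <- numeric(B)
    for (s in seq_len(B)) {
      Xs <- X[, ((s - 1) * L + 1):(s * L)]
      out[s] <- f1(Xs) + f1(rc_mat(Xs))
    }
    out
  }
  grad <- function(X) {
    B <- ncol(X) / L
    out <- matrix(0, 4, ncol(X))
    for (s in seq_len(B)) {
      cols <- ((s - 1) * L + 1):(s * L)
      out[, cols] <- W + rc_mat(W)
    }
    out
  }
  s <- random_dna(1, L, seed = 7)
  src <- reverse_complement(s)
  x <- t(one_hot_encode(s))
  refs <- lapply(dinucleotide_shuffle(s, n = 5, seed = 2),
                 function(r) t(one_hot_encode(r)))
  refs_rc <- lapply(refs, rc_mat)
  ig_f <- integrated_gradients(f, grad, x, refs, steps = 3)
  ig_r <- integrated_gradients(f, grad, t(one_hot_encode(src)), refs_rc,
                               steps = 3)
  expect_equal(ig_r$actual,
               ig_f$actual[rev(seq_len(nrow(ig_f$actual))), 4:1],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("contribution scores of a trained model satisfy completeness and
           highlight the planted motif", {
  m <- tiny_trained_model()
  set.seed(22)
  s <- random_dna(1, 81)
  pos <- 30L
  s <- paste0(substr(s, 1, pos - 1), "GGGGTAAC", substr(s, pos + 8, 81))
  cm <- contribution_scores(m, s, n_refs = 20, steps = 64, seed = 5)
  expect_s3_class(cm, "contribution_map")
  expect_equal(dim(cm$actual), c(81L, 4L))
  expect_equal(cm$actual, cm$hypothetical * one_hot_encode(s))
  expect_lt(cm$completeness_error, 0.05)
  # motif positions carry more attribution than the background
  motif_rows <- pos:(pos + 7)
  motif_mean <- mean(abs(rowSums(cm$actual[motif_rows, ])))
  bg_mean <- mean(abs(rowSums(cm$actual[-motif_rows, ])))
  expect_gt(motif_mean, bg_mean)
  expect_error(contribution_scores(build_model(tiny_spec(), 1), s),
               "trained")
})

test_that("contribution maps average elementwise across folds", {
  m <- tiny_trained_model()
  s <- random_dna(1, 81, seed = 30)
  maps <- lapply(1:3, function(i)
    contribution_scores(m, s, n_refs = 4, steps = 8, seed = i))
  avg <- average_contributions(maps)
  expect_equal(avg$actual,
               (maps[[1]]$actual + maps[[2]]$actual + maps[[3]]$actual) / 3)
  expect_equal(average_contributions(maps[c(1, 1)])$actual, maps[[1]]$actual)
  flip <- maps[[1]]
  flip$actual <- -flip$actual
  flip$hypothetical <- -flip$hypothetical
  expect_equal(max(abs(average_contributions(list(maps[[1]], flip))$actual)), 0)
  wrong <- maps[[1]]
  wrong$seq <- substr(wrong$seq, 1, 50)
  wrong$actual <- wrong$actual[1:50, ]
  expect_error(average_contributions(list(maps[[1]], wrong)), "share")
})

test_that("PWM information content and flank trimming behave as specified", {
  # pure-base position has IC 2; uniform has IC 0
  expect_equal(pwm_ic(matrix(c(1, 0, 0, 0), 1)), 2)
  expect_equal(pwm_ic(matrix(0.25, 1, 4)), 0)
  uni <- matrix(0.25, 5, 4)
  tr <- trim_pwm(uni)
  expect_equal(nrow(tr), 0)
  expect_true(attr(tr, "empty"))
  # build positions with prescribed ICs around the 0.4 threshold
  p_for_ic <- function(target) {
    f <- function(p) 2 + p * log2(p) + 3 * ((1 - p) / 3) * log2((1 - p) / 3) -
      target
    p <- stats::uniroot(f, c(0.2500001, 0.9999))$root
    c(p, rep((1 - p) / 3, 3))
  }
  pure <- c(1, 0, 0, 0)  # IC exactly 2
  pwm <- rbind(p_for_ic(0.1), pure, p_for_ic(0.1), pure, p_for_ic(0.3))
  ic <- pwm_ic(pwm)
  expect_equal(ic, c(0.1, 2, 0.1, 2, 0.3), tolerance = 1e-3,
               ignore_attr = TRUE)
  trimmed <- trim_pwm(pwm, 0.4)
  # flanks below 0.4 removed; the interior low-IC position 3 retained
  expect_equal(nrow(trimmed), 3)
  expect_equal(pwm_ic(trimmed), ic[2:4], tolerance = 1e-6)
  # fully informative PWM is untouched
  strong <- consensus_pwm("ACGT")
  expect_equal(trim_pwm(strong), strong, ignore_attr = TRUE)
})

test_that("MEME minimal text round-trips PWMs", {
  pwms <- list(motif_a = consensus_pwm("GGGGTAAC"),
               motif_b = consensus_pwm("TGA", p = 0.7))
  f <- tempfile(fileext = ".meme")
  write_meme(pwms, f)
  back <- read_meme(f)
  expect_identical(names(back), names(pwms))
  expect_equal(back$motif_a, pwms$motif_a, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$motif_b, pwms$motif_b, tolerance = 1e-5,
               ignore_attr = TRUE)
})
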
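test_that("architecture spec reproduces the published layout and scales", {
  s <- architecture_spec()
  expect_equal(s$conv_filters, c(256L, 120L, 60L, 60L))
  expect_equal(s$conv_widths, c(7L, 3L, 3L, 3L))
  expect_equal(s$dense_units, c(64L, 256L))
  expect_equal(s$dropout, 0.4)
  s2 <- architecture_spec(width_scale = 0.25)
  expect_equal(s2$conv_filters, c(64L, 30L, 15L, 15L))
  expect_error(architecture_spec(input_length = 50), "minimum")
  expect_error(architecture_spec(dropout = 1), "dropout")
  expect_error(architecture_spec(conv_filters = c(8, 8), conv_widths = 3),
               "equal length")
})

test_that("trainable parameter count matches closed-form layer arithmetic", {
  count_oracle <- function(spec) {
    n <- 0; cin <- 4; L <- spec$input_length
    for (i in seq_along(spec$conv_filters)) {
      f <- spec$conv_filters[i]; k <- spec$conv_widths[i]
      n <- n + f * cin * k + f + 2 * f    # W, b, gamma, beta
      cin <- f; L <- L %/% 3
    }
    din <- cin * L
    for (u in spec$dense_units) {
      n <- n + u * din + u + 2 * u
      din <- u
    }
    n + din + 1
  }
  set.seed(31)
  for (i in 1:8) {
    nl <- sample(2:3, 1)
    spec <- architecture_spec(
      input_length = sample(c(81, 243, 1001), 1),
      conv_filters = sample(3:12, nl, replace = TRUE),
      conv_widths = c(7, 3, 3)[seq_len(nl)],
      dense_units = sample(3:20, sample(1:2, 1)))
    m <- build_model(spec, seed = i)
    expect_equal(n_params(m), count_oracle(spec))
  }
  # the stated tiny example: one conv(4 filters, width 3), one dense(2), L=9
  spec <- architecture_spec(input_length = 9, conv_filters = 4,
                            conv_widths = 3, dense_units = 2)
  # conv: 4*(4*3)+4+8 = 60; flat = 4*(9%/%3) = 12; dense: 2*12+2+4 = 30;
  # head: 2+1 = 3
  expect_equal(n_params(build_model(spec, 1)), 60 + 30 + 3)
})

test_that("training is deterministic and obeys the patience contract", {
  task <- toy_motif_task(n = 80)
  m <- build_model(tiny_spec(), seed = 2)
  cfg <- train_config(batch_size = 32, patience = 3, max_epochs = 6, seed = 5)
  f1 <- train_cnn(m, task$seqs[1:60], task$y[1:60],
                  task$seqs[61:80], task$y[61:80], cfg)
  f2 <- train_cnn(m, task$seqs[1:60], task$y[1:60],
                  task$seqs[61:80], task$y[61:80], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  # constant targets with patience 1: the loss cannot keep improving, so
  # training stops within a couple of epochs
  cfg1 <- train_config(batch_size = 32, patience = 1, max_epochs = 50, seed = 1)
  fc <- train_cnn(m, task$seqs[1:60], rep(1.5, 60),
                  task$seqs[61:80], rep(1.5, 20), cfg1)
  # with patience 1, training ends one epoch after the last improvement
  expect_identical(fc$meta$stop_reason, "early_stop")
  expect_equal(nrow(fc$history), fc$meta$best_epoch + 1L)
})

test_that("training validates inputs", {
  m <- build_model(tiny_spec(), seed = 1)
  expect_error(train_cnn(m, character(0), numeric(0), "A", 1), "empty")
  mc <- build_model(tiny_spec(head = "sigmoid"), seed = 1)
  task <- toy_motif_task(n = 40)
  expect_error(train_cnn(mc, task$seqs, task$y, task$seqs, task$y,
                         train_config(loss = "mse")), "bce")
  expect_error(train_cnn(mc, task$seqs, rep(0, 40), task$seqs[1:5], rep(0, 5),
                         train_config(loss = "bce")), "degenerate")
  expect_error(predict(m, "ACGT"), "length")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(9)
  spec <- tiny_spec()
  m <- build_model(spec, seed = 5)
  seqs <- random_dna(16, 81)
  codes <- enforge:::seqs_to_codes(seqs, 81)
  y <- rnorm(16)
  arch <- enforge:::.arch_for_cpp(m)
  g <- enforge:::cpp_cnn_loss_grad(m$params, arch, codes, y, "mse")
  perturb <- function(params, where, i, e) {
    if (where[[1]] == "head") params$head[[where[[2]]]][i] <-
        params$head[[where[[2]]]][i] + e
    else params[[where[[1]]]][[where[[2]]]][[where[[3]]]][i] <-
        params[[where[[1]]]][[where[[2]]]][[where[[3]]]][i] + e
    params
  }
  fd <- function(where, i, eps = 3e-3) {
    (enforge:::cpp_cnn_loss(perturb(m$params, where, i, eps), arch, codes, y, "mse") -
     enforge:::cpp_cnn_loss(perturb(m$params, where, i, -eps), arch, codes, y, "mse")) /
      (2 * eps)
  }
  set.seed(2)
  for (where in list(list("conv", 1, "W"), list("conv", 2, "W"),
                     list("conv", 1, "gamma"), list("dense", 1, "W"),
                     list("dense", 1, "beta"), list("head", "W"))) {
    gm <- if (where[[1]] == "head") g$head[[where[[2]]]]
          else g[[where[[1]]]][[where[[2]]]][[where[[3]]]]
    idx <- sample(length(gm), min(5, length(gm)))
    rel <- vapply(idx, function(i)
      abs(fd(where, i) - gm[i]) / max(abs(gm[i]), 1e-2), numeric(1))
    # median over sampled coordinates guards against ReLU/pool kink noise
    expect_lt(median(rel), 0.05)
  }
})

test_that("convergence filter applies the strict thresholds", {
  mk <- function(metric) {
    m <- build_model(tiny_spec(), seed = 1)
    m$meta$metric <- metric
    m
  }
  kept <- convergence_filter(lapply(c(0.7, 0.05, 0.68), mk), "regression")
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(m) m$meta$metric, numeric(1)),
               c(0.7, 0.68))
  expect_length(convergence_filter(lapply(c(0.5, 0.2), mk), "regression"), 2)
  # classification boundary: AUC of exactly 0.70 is dropped
  kept2 <- convergence_filter(lapply(c(0.71, 0.70), mk), "classification")
  expect_length(kept2, 1)
  expect_equal(kept2[[1]]$meta$metric, 0.71)
  expect_error(convergence_filter(lapply(c(0.05, 0.1), mk), "regression"),
               "no converged")
})

test_that("ensemble prediction is the replicate mean", {
  set.seed(12)
  models <- lapply(1:3, function(i) build_model(tiny_spec(), seed = i))
  ens <- cnn_ensemble(models)
  seqs <- random_dna(10, 81)
  per_model <- vapply(models, function(m) predict(m, seqs), numeric(10))
  expect_equal(predict(ens, seqs), rowMeans(per_model))
  # permutation invariance and min/max bounds
  ens2 <- cnn_ensemble(models[c(3, 1, 2)])
  expect_equal(predict(ens2, seqs), predict(ens, seqs))
  expect_true(all(predict(ens, seqs) >= apply(per_model, 1, min) - 1e-8))
  expect_true(all(predict(ens, seqs) <= apply(per_model, 1, max) + 1e-8))
  # single member is the identity
  expect_equal(predict(cnn_ensemble(models[1]), seqs), per_model[, 1])
})

test_that("genome-wide tiled prediction equals the per-base mean oracle", {
  m <- build_model(tiny_spec(input_length = 81), seed = 4)
  set.seed(8)
  g <- c(chrZ = random_dna(1, 230))
  stride <- 20L
  track <- predict_genome(m, g, stride = stride)
  # oracle: enumerate windows, score, average per base
  starts <- seq(1L, 230L - 81L + 1L, by = stride)
  preds <- predict(m, substring(g[[1]], starts, starts + 80L))
  acc <- numeric(230); cnt <- numeric(230)
  for (i in seq_along(starts)) {
    span <- starts[i]:(starts[i] + 80L)
    acc[span] <- acc[span] + preds[i]
    cnt[span] <- cnt[span] + 1
  }
  oracle <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  expect_equal(track$chrZ, oracle, tolerance = 1e-6)
  # uncovered tail positions are NA
  expect_true(all(is.na(track$chrZ[(max(starts) + 81L):230L])))
  # short chromosome: all NA
  g2 <- c(s = random_dna(1, 50))
  expect_true(all(is.na(predict_genome(m, g2)$s)))
})

test_that("pearson wraps cor with validation", {
  x <- rnorm(20)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  # 20-point hand-computed oracle
  set.seed(77)
  y <- rnorm(20)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), oracle)
  expect_error(pearson(x, rep(1, 20)), "constant")
  expect_error(pearson(1, 2), "two observations")
})

test_that("models save and load with a JSON manifest", {
  m <- tiny_trained_model()
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, random_dna(3, 81, seed = 1)),
               predict(m, random_dna(3, 81, seed = 1)))
  man <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(man$spec$input_length, 81)
  expect_equal(man$auc_definition, "ROC")
})
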
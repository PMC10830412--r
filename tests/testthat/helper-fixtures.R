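# shared tiny fixtures; heavyweight trained-model fixtures are memoized in
# .fixture_env so expensive training happens at most once per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# minimal architecture that trains in well under a second
tiny_spec <- function(input_length = 81L, head = "linear", dropout = 0) {
  architecture_spec(input_length = input_length,
                    conv_filters = c(8L, 6L), conv_widths = c(7L, 3L),
                    dense_units = c(8L), dropout = dropout, head = head)
}

# toy task: y = 2 * (planted consensus motif present) + noise
toy_motif_task <- function(n = 240, len = 81, motif = "GGGGTAAC", seed = 4,
                           binary = FALSE) {
  set.seed(seed)
  seqs <- random_dna(n, len)
  lab <- rbinom(n, 1, 0.5)
  seqs[lab == 1] <- vapply(seqs[lab == 1], function(s) {
    p <- sample.int(len - nchar(motif), 1)
    paste0(substr(s, 1, p - 1), motif, substr(s, p + nchar(motif), len))
  }, character(1))
  y <- if (binary) lab else 2 * lab + rnorm(n, 0, 0.1)
  list(seqs = seqs, y = y, lab = lab)
}

# a trained tiny regression model on the toy motif task (memoized)
tiny_trained_model <- function() {
  memo("tiny_trained_model", {
    task <- toy_motif_task(n = 800)
    m <- build_model(tiny_spec(), seed = 3)
    cfg <- train_config(learning_rate = 0.005, batch_size = 32,
                        patience = 10, max_epochs = 60, seed = 7)
    train_cnn(m, task$seqs[1:700], task$y[1:700],
              task$seqs[701:760], task$y[701:760], cfg)
  })
}

# small genome + constant-free coverage fixture for interval arithmetic
toy_track <- function(lens = c(chr1 = 3000L, chr2 = 2500L), seed = 1) {
  set.seed(seed)
  lapply(lens, function(L) runif(L, 0, 4))
}

# ---- desk-scale study fixtures (shared across the acceptance checks) -------
# one synthetic world at the package's default study conditions, its
# regression dataset, and models trained on held-out fold 1

study_world <- function() {
  memo("study_world", {
    w <- make_world(world_config(seed = 11L))
    ds <- build_regression_dataset(w, seed = 11L)
    labels <- label_records(w$activity, world_term_map(w))
    list(w = w, ds = ds, labels = labels)
  })
}

study_access_model <- function() {
  memo("study_access_model", {
    sw <- study_world()
    m <- build_model(architecture_spec(width_scale = 0.25), seed = 11L)
    train_on_fold(m, sw$ds, test_fold = 1L,
                  train_config(seed = 11L, patience = 10L, max_epochs = 30L))
  })
}

study_activity_dataset <- function(tissue = "cns") {
  memo(paste0("study_act_", tissue), {
    sw <- study_world()
    build_activity_dataset(sw$labels, tissue, sw$w$genome,
                           sw$w$peaks[[tissue]], sw$ds$fold_plan, seed = 11L)
  })
}

study_activity_model <- function() {
  memo("study_activity_model", {
    fine_tune(study_access_model(), study_activity_dataset(), test_fold = 1L,
              config = train_config(learning_rate = 1e-4, loss = "bce",
                                    patience = 20L, max_epochs = 40L),
              seed = 1L)
  })
}
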
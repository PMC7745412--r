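test_that("split_dataset follows the one-third validation rule, stratified", {
  ds <- tiny_motif_dataset(45L, L = 30L, seed = 1)   # 45/45
  sp <- split_dataset(ds, val_fraction = 1 / 3, seed = 5)
  expect_length(sp$train, 60L)
  expect_length(sp$validation, 30L)
  expect_identical(sum(sp$train$label == 1L), 30L)
  expect_identical(sum(sp$validation$label == 1L), 15L)
  # same seed, same partitions
  sp2 <- split_dataset(ds, val_fraction = 1 / 3, seed = 5)
  expect_identical(sp$train$id, sp2$train$id)
  expect_identical(sp$validation$id, sp2$validation$id)
})

test_that("splits partition the dataset: disjoint, union-complete", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    ds <- tiny_motif_dataset(n, L = 25L, seed = i)
    tf <- sample(c(0, 0.2, 0.3), 1)
    sp <- split_dataset(ds, val_fraction = runif(1, 0.2, 0.5),
                        test_fraction = tf, seed = i)
    ids <- c(sp$train$id, sp$validation$id, sp$test$id)
    expect_identical(anyDuplicated(ids), 0L)
    expect_setequal(ids, ds$id)
  }
  tiny <- new_labeled_dataset(id = c("a", "b"), sequence = c("ACGU", "AAAA"),
                              label = c(1L, 0L))
  expect_error(split_dataset(tiny), class = "kmerbind_stratification_error")
})

test_that("one-hot encoding is the identity code and round-trips", {
  m <- one_hot_encode("ACGU")
  expect_equal(unname(m), diag(4))
  set.seed(4)
  for (i in 1:10) {
    s <- random_rna(sample(5:40, 1))
    enc <- one_hot_encode(s)
    expect_true(all(rowSums(enc) == 1))
    expect_identical(one_hot_decode(enc), s)
  }
  expect_error(one_hot_encode("ACGT"), class = "kmerbind_alphabet_error")
})

test_that("compute_auc equals exhaustive pair counting and is rank-invariant", {
  expect_identical(compute_auc(c(1, 1, 0, 0), c(.9, .8, .2, .1)), 1)
  expect_identical(compute_auc(c(1, 0), c(.5, .5)), 0.5)
  # brute-force oracle over all positive-negative pairs (ties count half)
  brute <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_identical(compute_auc(c(1, 0, 1, 0), c(.9, .8, .7, .1)),
                   brute(c(1, 0, 1, 0), c(.9, .8, .7, .1)))   # 0.75
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(y[-(1:2)], 0, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # rounding induces ties
    expect_equal(compute_auc(y, s), brute(y, s), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(compute_auc(y, qlogis(s * 0.98 + 0.01)), compute_auc(y, s),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(c(1, 1), c(.2, .3)), class = "kmerbind_undefined_auc")
})

test_that("compute_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- rbinom(120, 1, 0.5); s <- runif(120) + 0.3 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(compute_auc(y, s), ref, tolerance = 1e-12)
})

test_that("training runs the requested epochs and records history", {
  ds <- tiny_motif_dataset(12L, L = 30L, seed = 8)
  sp <- split_dataset(ds, 1 / 3, seed = 2)
  emb <- train_embeddings(sp$train, skipgram_config(dim = 6, epochs = 1, seed = 1))
  cfg <- model_config(variant = "no_structure", kernel_widths = c(3, 3, 3),
                      filters = 3, lstm_units = 2, fc_units = 4,
                      input_dim_seq = 6, seed = 3)
  tcfg <- train_config(epochs = 1L, batch_size = 8L, patience = 0L, seed = 4)
  mod <- train_model(cfg, tcfg, sp, emb)
  expect_identical(nrow(mod$history), 1L)
  expect_identical(mod$best_epoch, 1L)
  pred <- predict_dataset(mod, sp$validation, emb)
  expect_identical(pred$id, sp$validation$id)
  expect_true(all(pred$score > 0 & pred$score < 1))
})

test_that("training is bitwise-reproducible under identical seeds", {
  ds <- tiny_motif_dataset(10L, L = 25L, seed = 6)
  sp <- split_dataset(ds, 1 / 3, seed = 2)
  emb <- train_embeddings(sp$train, skipgram_config(dim = 5, epochs = 1, seed = 1))
  cfg <- model_config(variant = "no_structure", kernel_widths = c(3, 3, 3),
                      filters = 2, lstm_units = 2, fc_units = 3,
                      input_dim_seq = 5, seed = 3)
  tcfg <- train_config(epochs = 2L, batch_size = 8L, patience = 0L, seed = 4)
  m1 <- train_model(cfg, tcfg, sp, emb)
  m2 <- train_model(cfg, tcfg, sp, emb)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  p1 <- predict_dataset(m1, sp$validation, emb)
  p2 <- predict_dataset(m2, sp$validation, emb)
  expect_identical(p1$score, p2$score)
})

test_that("variants requiring structure fail cleanly on shape-free data", {
  ds <- tiny_motif_dataset(10L, L = 25L, seed = 9)
  sp <- split_dataset(ds, 1 / 3, seed = 1)
  emb <- train_embeddings(sp$train, skipgram_config(dim = 5, epochs = 0, seed = 1))
  cfg <- model_config(variant = "full", kernel_widths = c(3, 3, 3), filters = 2,
                      lstm_units = 2, input_dim_seq = 5, input_dim_struct = 5,
                      seed = 2)
  expect_error(train_model(cfg, train_config(epochs = 1, seed = 1), sp, emb),
               class = "kmerbind_missing_structure")
  expect_error(run_ablation(ds, "full"), class = "kmerbind_missing_structure")
})
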
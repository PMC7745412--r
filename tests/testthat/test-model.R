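scalar_lstm_weights <- function(W = 0.5, U = 0.3, b = 0.1) {
  list(W_f = matrix(W), W_i = matrix(W + 0.1), W_c = matrix(W - 0.2),
       W_o = matrix(W + 0.05),
       U_f = matrix(U), U_i = matrix(U - 0.1), U_c = matrix(U + 0.2),
       U_o = matrix(U + 0.05),
       b_f = b, b_i = b + 0.1, b_c = b - 0.1, b_o = b)
}

test_that("lstm_step with zero weights yields gates 0.5 and zero state", {
  w <- list(W_f = matrix(0, 2, 3), W_i = matrix(0, 2, 3), W_c = matrix(0, 2, 3),
            W_o = matrix(0, 2, 3),
            U_f = matrix(0, 2, 2), U_i = matrix(0, 2, 2), U_c = matrix(0, 2, 2),
            U_o = matrix(0, 2, 2),
            b_f = c(0, 0), b_i = c(0, 0), b_c = c(0, 0), b_o = c(0, 0))
  st <- lstm_step(c(1, -2, 3), list(h = c(0, 0), c = c(0, 0)), w)
  expect_equal(st$f, c(0.5, 0.5))
  expect_equal(st$i, c(0.5, 0.5))
  expect_equal(st$o, c(0.5, 0.5))
  expect_equal(st$c, c(0, 0))
  expect_equal(st$h, c(0, 0))
})

test_that("scalar lstm_step matches a hand computation of the gated update", {
  w <- scalar_lstm_weights()
  x <- 0.7; h0 <- 0.2; c0 <- -0.4
  st <- lstm_step(x, list(h = h0, c = c0), w)
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(0.5 * x + 0.3 * h0 + 0.1)
  i <- sg(0.6 * x + 0.2 * h0 + 0.2)
  g <- tanh(0.3 * x + 0.5 * h0 + 0)   # b_c = 0.1 - 0.1
  o <- sg(0.55 * x + 0.35 * h0 + 0.1)
  ct <- f * c0 + i * g
  expect_equal(drop(st$c), ct, tolerance = 1e-10)
  expect_equal(drop(st$h), o * tanh(ct), tolerance = 1e-10)
})

test_that("lstm gates saturate toward 1 under strongly positive drive", {
  w <- scalar_lstm_weights(W = 50, U = 0, b = 0)
  st <- lstm_step(10, list(h = 0, c = 0), w)
  expect_true(all(abs(c(st$f, st$i, st$o) - 1) < 1e-6))
})

test_that("the production LSTM layer agrees with unrolled lstm_step calls", {
  set.seed(21)
  u <- 3L; Cin <- 4L; Tt <- 6L
  Wx <- matrix(rnorm(Cin * 4 * u) * 0.4, Cin, 4 * u)
  Wh <- matrix(rnorm(u * 4 * u) * 0.4, u, 4 * u)
  b <- rnorm(4 * u) * 0.2
  X <- array(rnorm(Tt * 1 * Cin), c(Tt, 1, Cin))
  out <- kmerbind:::lstm_forward(X, Tt, Wx, Wh, b)
  # map fused [f|i|g|o] weights onto the didactic per-gate form
  idx <- function(k) ((k - 1) * u + 1):(k * u)
  w <- list(W_f = t(Wx[, idx(1)]), W_i = t(Wx[, idx(2)]),
            W_c = t(Wx[, idx(3)]), W_o = t(Wx[, idx(4)]),
            U_f = t(Wh[, idx(1)]), U_i = t(Wh[, idx(2)]),
            U_c = t(Wh[, idx(3)]), U_o = t(Wh[, idx(4)]),
            b_f = b[idx(1)], b_i = b[idx(2)], b_c = b[idx(3)], b_o = b[idx(4)])
  st <- list(h = numeric(u), c = numeric(u))
  for (t in seq_len(Tt)) st <- lstm_step(X[t, 1, ], st, w)
  expect_equal(drop(out$h), st$h, tolerance = 1e-5)
})

test_that("build_model wires variants and seeds deterministically", {
  cfg <- model_config(lstm_units = 32, input_dim_seq = 10, input_dim_struct = 10,
                      seed = 4)
  m <- build_model(cfg)
  # 32 units per direction concatenate to a 64-wide recurrent feature block,
  # joined with the pooled convolution features ahead of fc1
  expect_identical(ncol(m$params$lstm_f_Wh), 4L * 32L)
  expect_identical(nrow(m$params$fc1_W), cfg$filters + 64L)
  # cnn_only has no recurrent parameters
  m2 <- build_model(model_config(variant = "cnn_only", input_dim_seq = 10,
                                 input_dim_struct = 10, seed = 4))
  expect_false(any(grepl("lstm", names(m2$params))))
  # no_structure drops the structure branch
  m3 <- build_model(model_config(variant = "no_structure", input_dim_seq = 10,
                                 seed = 4))
  expect_false(any(grepl("struct", names(m3$params))))
  # one_hot forces 4 input channels
  m4 <- build_model(model_config(variant = "one_hot", seed = 4))
  expect_identical(nrow(m4$params$conv_seq_W),
                   4L * m4$config$kernel_widths[1])
  # determinism of initialization
  mA <- build_model(cfg); mB <- build_model(cfg)
  expect_identical(mA$params, mB$params)
  mC <- build_model(model_config(lstm_units = 32, input_dim_seq = 10,
                                 input_dim_struct = 10, seed = 5))
  expect_false(identical(mA$params$fc1_W, mC$params$fc1_W))
  expect_error(model_config(variant = "bogus"), class = "kmerbind_config_error")
})

test_that("pad_and_mask pads right with zeros and unpad round-trips", {
  set.seed(2)
  ex <- lapply(c(10L, 7L, 7L), function(L) matrix(rnorm(L * 3), L, 3))
  pm <- pad_and_mask(ex)
  expect_identical(dim(pm$X), c(10L, 3L, 3L))
  expect_identical(pm$lens, c(10L, 7L, 7L))
  expect_true(all(pm$X[8:10, 2, ] == 0))
  back <- unpad_batch(pm$X, pm$lens)
  for (b in 1:3) expect_equal(back[[b]], ex[[b]], tolerance = 1e-15)
  # single example: no-op
  pm1 <- pad_and_mask(ex[1])
  expect_equal(pm1$X[, 1, ], ex[[1]], tolerance = 1e-15)
  expect_error(pad_and_mask(list()), class = "kmerbind_empty_batch")
})

test_that("max-pool halves the grid with pool width 2", {
  set.seed(8)
  X <- abs(array(rnorm(9 * 2 * 3), c(9, 2, 3)))
  pl <- kmerbind:::maxpool_forward(kmerbind:::mask_positions(X, c(9L, 6L)),
                                   c(9L, 6L), 2L)
  expect_identical(dim(pl$out)[1], 9L %/% 2L)
  expect_identical(pl$lens, c(4L, 3L))
})

make_toy_batch <- function(cfg, lens, with_struct, seed = 31) {
  set.seed(seed)
  pm <- pad_and_mask(lapply(lens, function(L)
    matrix(rnorm(L * cfg$input_dim_seq) * 0.5, L, cfg$input_dim_seq)))
  batch <- list(X_seq = pm$X, X_struct = NULL, lens = pm$lens)
  if (with_struct) {
    pm2 <- pad_and_mask(lapply(lens, function(L)
      matrix(rnorm(L * cfg$input_dim_struct) * 0.5, L, cfg$input_dim_struct)))
    batch$X_struct <- pm2$X
  }
  batch
}

test_that("forward yields probabilities strictly inside (0,1), equal for duplicates", {
  cfg <- model_config(kernel_widths = c(3, 5, 4), filters = 4, lstm_units = 3,
                      fc_units = 6, dropout = 0, input_dim_seq = 5,
                      input_dim_struct = 5, seed = 13)
  m <- build_model(cfg)
  batch <- make_toy_batch(cfg, c(12L, 12L, 9L), with_struct = TRUE)
  batch$X_seq[, 2, ] <- batch$X_seq[, 1, ]    # duplicate example 1 as 2
  batch$X_struct[, 2, ] <- batch$X_struct[, 1, ]
  p <- model_forward(m, batch)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[1], p[2], tolerance = 1e-12)
})

test_that("predictions are invariant to how far the batch is padded", {
  cfg <- model_config(kernel_widths = c(8, 16, 32), filters = 6, lstm_units = 4,
                      fc_units = 8, dropout = 0, input_dim_seq = 5,
                      input_dim_struct = 5, seed = 3)
  m <- build_model(cfg)
  set.seed(44)
  L <- 60L
  ex <- matrix(rnorm(L * 5), L, 5); ex2 <- matrix(rnorm(L * 5), L, 5)
  mkb <- function(pad) {
    X <- array(0, c(L + pad, 1, 5)); X[1:L, 1, ] <- ex
    Xs <- array(0, c(L + pad, 1, 5)); Xs[1:L, 1, ] <- ex2
    list(X_seq = X, X_struct = Xs, lens = L)
  }
  p0 <- model_forward(m, mkb(0L))
  p40 <- model_forward(m, mkb(40L))
  p100 <- model_forward(m, mkb(100L))
  expect_equal(p0, p40, tolerance = 1e-5)
  expect_equal(p0, p100, tolerance = 1e-5)
})

test_that("backpropagation matches central differences for every variant", {
  set.seed(5)
  for (variant in c("full", "no_structure", "one_hot", "cnn_only")) {
    cfg <- model_config(variant = variant, kernel_widths = c(3, 5, 4),
                        filters = 3, lstm_units = 4, fc_units = 5, dropout = 0,
                        input_dim_seq = 6, input_dim_struct = 6, seed = 11)
    m <- build_model(cfg)
    batch <- make_toy_batch(cfg, c(9L, 13L),
                            with_struct = variant %in% c("full", "cnn_only"))
    y <- c(1, 0)
    lg <- kmerbind:::network_loss_grads(m$params, cfg, batch, y)
    worst <- 0
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(4L, length(p)))) {
        h <- 1e-5
        pp <- m$params; pp[[nm]][i] <- p[i] + h
        lp <- kmerbind:::network_loss_grads(pp, cfg, batch, y)$loss
        pp[[nm]][i] <- p[i] - h
        lm <- kmerbind:::network_loss_grads(pp, cfg, batch, y)$loss
        num <- (lp - lm) / (2 * h)
        ana <- lg$grads[[nm]][i]
        if (abs(num - ana) > 1e-8)
          worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("dimension and structure errors are reported", {
  cfg <- model_config(kernel_widths = c(3, 3, 3), filters = 3, lstm_units = 2,
                      input_dim_seq = 5, input_dim_struct = 5, dropout = 0,
                      seed = 1)
  m <- build_model(cfg)
  batch <- make_toy_batch(cfg, c(10L, 10L), with_struct = FALSE)
  expect_error(model_forward(m, batch), class = "kmerbind_missing_structure")
  bad <- make_toy_batch(model_config(input_dim_seq = 7, input_dim_struct = 7,
                                     dropout = 0, seed = 1),
                        c(10L, 10L), with_struct = TRUE)
  expect_error(model_forward(m, bad), class = "kmerbind_dimension_error")
})
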
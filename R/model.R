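# The classifier network: two feature-extraction convolution branches (one on
# the embedded sequence 3-mers, one on the embedded shape 3-mers), channel
# concatenation, a joint convolution capturing sequence-structure interplay,
# a bidirectional LSTM whose per-position hidden states (the two directions
# concatenated, 64 features for 32 units each) are max-pooled over valid
# positions, two dense layers and a sigmoid output. Ablation variants:
# `no_structure` drops
# the structure branch, `one_hot` additionally replaces embeddings with the
# 4-channel identity code, `cnn_only` replaces the BiLSTM with a global max
# over positions.
#
# Convolutions are length-preserving ('same' zero padding) so the two branch
# outputs align position-by-position for concatenation; positions past each
# example's true length are masked to zero before every pooling step and the
# recurrence runs on true lengths only, which makes predictions invariant to
# how far a batch is padded.

MODEL_VARIANTS <- c("full", "no_structure", "one_hot", "cnn_only")

#' Architecture configuration
#'
#' @param variant One of `"full"`, `"no_structure"`, `"one_hot"`, `"cnn_only"`.
#' @param kernel_widths Three convolution widths: sequence branch, structure
#'   branch, joint module (defaults 8, 16, 32).
#' @param filters Convolution channels per module.
#' @param pool_width Max-pool window (default 2).
#' @param lstm_units Hidden units per LSTM direction (default 32, so the
#'   concatenated bidirectional output has 64 features).
#' @param fc_units Width of the first dense layer.
#' @param dropout Dropout probability on the pooled convolution features.
#' @param recurrent_dropout Dropout probability on the pooled bidirectional
#'   LSTM features (training only). The recurrent block is four times wider
#'   than the convolution block and can overfit small datasets quickly; the
#'   heavier dropout keeps it from outracing the convolutional features.
#' @param input_dim_seq,input_dim_struct Embedding dimensions of the two
#'   inputs; `one_hot` forces `input_dim_seq = 4`.
#' @param seed Seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = "full", kernel_widths = c(8L, 16L, 32L),
                         filters = 64L, pool_width = 2L, lstm_units = 32L,
                         fc_units = 64L, dropout = 0.25,
                         recurrent_dropout = 0.5, input_dim_seq = 30L,
                         input_dim_struct = 30L, seed = 1L) {
  if (!variant %in% MODEL_VARIANTS)
    abort("kmerbind_config_error", "unknown variant '%s' (use %s)", variant,
          paste(MODEL_VARIANTS, collapse = ", "))
  stopifnot(length(kernel_widths) == 3L, all(kernel_widths >= 1L),
            filters >= 1L, pool_width >= 1L, lstm_units >= 1L, fc_units >= 1L,
            dropout >= 0, dropout < 1, recurrent_dropout >= 0,
            recurrent_dropout < 1)
  if (variant == "one_hot") input_dim_seq <- 4L
  structure(list(variant = variant, kernel_widths = as.integer(kernel_widths),
                 filters = as.integer(filters), pool_width = as.integer(pool_width),
                 lstm_units = as.integer(lstm_units), fc_units = as.integer(fc_units),
                 dropout = dropout, recurrent_dropout = recurrent_dropout,
                 input_dim_seq = as.integer(input_dim_seq),
                 input_dim_struct = as.integer(input_dim_struct),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @keywords internal
#' @noRd
has_structure_branch <- function(cfg) cfg$variant %in% c("full", "cnn_only")

#' Build an untrained model with seeded initial weights
#'
#' Weights use Glorot-uniform initialization, except the recurrent matrices,
#' which start at a tenth of the Glorot scale so the untrained layer is
#' nearly feed-forward; all biases start at 0. Two builds with the same seed
#' are identical.
#'
#' @param cfg A [model_config()].
#' @return A `kmerbind_model`: list with `config` and named `params`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  Fo <- cfg$filters; u <- cfg$lstm_units
  with_seed(cfg$seed, {
    p <- list()
    p$conv_seq_W <- glorot(cfg$kernel_widths[1L] * cfg$input_dim_seq, Fo)
    p$conv_seq_b <- numeric(Fo)
    if (has_structure_branch(cfg)) {
      p$conv_struct_W <- glorot(cfg$kernel_widths[2L] * cfg$input_dim_struct, Fo)
      p$conv_struct_b <- numeric(Fo)
    }
    Cj <- if (has_structure_branch(cfg)) 2L * Fo else Fo
    p$conv_joint_W <- glorot(cfg$kernel_widths[3L] * Cj, Fo)
    p$conv_joint_b <- numeric(Fo)
    feat_dim <- if (cfg$variant == "cnn_only") Fo else Fo + 2L * u
    if (cfg$variant != "cnn_only") {
      for (dir in c("f", "b")) {
        p[[paste0("lstm_", dir, "_Wx")]] <- glorot(Fo, 4L * u)
        # recurrent weights start small so the untrained layer is nearly
        # feed-forward: the convolution filters then receive clean gradient
        # early on and the recurrence grows as it earns its keep
        p[[paste0("lstm_", dir, "_Wh")]] <- 0.1 * glorot(u, 4L * u)
        bias <- numeric(4L * u)   # forget bias 0: short memory at init, see vignette
        p[[paste0("lstm_", dir, "_b")]] <- bias
      }
    }
    p$fc1_W <- glorot(feat_dim, cfg$fc_units)
    p$fc1_b <- numeric(cfg$fc_units)
    p$fc2_W <- glorot(cfg$fc_units, 1L)
    p$fc2_b <- numeric(1L)
    structure(list(config = cfg, params = p), class = "kmerbind_model")
  })
}

#' @export
print.kmerbind_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<kmerbind_model> variant=%s, kernels=%s, filters=%d, lstm=%d, %d parameters\n",
              x$config$variant, paste(x$config$kernel_widths, collapse = "/"),
              x$config$filters, x$config$lstm_units, np))
  invisible(x)
}

#' Pad embedded examples into a batch tensor with a length mask
#'
#' Right-pads every example (a `T_i x d` matrix) with zero rows to the batch
#' maximum length and records true lengths.
#'
#' @param examples List of numeric matrices with a common column count.
#' @return List with `X`, a `(T_max, B, d)` array, and `lens`, the true row
#'   count of each example.
#' @export
pad_and_mask <- function(examples) {
  if (length(examples) == 0L) abort("kmerbind_empty_batch", "empty batch")
  lens <- vapply(examples, nrow, integer(1L))
  d <- ncol(examples[[1L]])
  Tm <- max(lens)
  X <- array(0, c(Tm, length(examples), d))
  for (b in seq_along(examples)) X[seq_len(lens[b]), b, ] <- examples[[b]]
  list(X = X, lens = lens)
}

#' Recover original matrices from a padded batch
#'
#' @param X `(T, B, d)` padded array.
#' @param lens True lengths.
#' @return List of `lens[b] x d` matrices.
#' @export
unpad_batch <- function(X, lens) {
  lapply(seq_along(lens), function(b)
    matrix(X[seq_len(lens[b]), b, ], lens[b], dim(X)[3L]))
}

#' One step of the LSTM recurrence
#'
#' Didactic single-step implementation of the gated update
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f),\quad
#'       i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i),}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_c x_t + U_c h_{t-1} + b_c),}
#' \deqn{o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o),\quad
#'       h_t = o_t \odot \tanh(c_t).}
#' The production layer is verified against an unrolled sequence of these
#' steps in the test suite.
#'
#' @param x_t Input vector at time t.
#' @param prev List with `h` and `c`, the previous state (vectors of length
#'   `units`).
#' @param w List of weights `W_f, W_i, W_c, W_o` (`units x length(x_t)`),
#'   `U_f, U_i, U_c, U_o` (`units x units`) and biases `b_f, b_i, b_c, b_o`.
#' @return List with `h`, `c` and gate activations `f`, `i`, `o`, `g`.
#' @export
lstm_step <- function(x_t, prev, w) {
  f <- sigmoid(drop(w$W_f %*% x_t + w$U_f %*% prev$h) + w$b_f)
  i <- sigmoid(drop(w$W_i %*% x_t + w$U_i %*% prev$h) + w$b_i)
  g <- tanh(drop(w$W_c %*% x_t + w$U_c %*% prev$h) + w$b_c)
  o <- sigmoid(drop(w$W_o %*% x_t + w$U_o %*% prev$h) + w$b_o)
  c_t <- f * prev$c + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, f = f, i = i, o = o, g = g)
}

# ---- full network forward / backward ---------------------------------------

# batch: list(X_seq (T,B,Cs), X_struct (T,B,Ct) or NULL, lens).
# Returns probabilities and the caches needed for the backward pass.
#' @keywords internal
#' @noRd
network_forward <- function(params, cfg, batch, training = FALSE) {
  pw <- cfg$pool_width
  lens0 <- batch$lens
  if (any(lens0 < pw * pw))
    abort("kmerbind_dimension_error",
          "an example has %d tokens; at least %d are required", min(lens0), pw * pw)
  if (dim(batch$X_seq)[3L] != cfg$input_dim_seq)
    abort("kmerbind_dimension_error", "sequence feature dimension %d != configured %d",
          dim(batch$X_seq)[3L], cfg$input_dim_seq)
  cc <- list()

  run_branch <- function(X, W, b, w) {
    cv <- conv1d_forward(X, W, b, w)
    relu_mask <- cv$out > 0
    A <- cv$out * relu_mask
    A <- mask_positions(A, lens0)
    pl <- maxpool_forward(A, lens0, pw)
    list(out = pl$out, lens = pl$lens,
         cache = list(conv = cv$cache, relu = relu_mask, pool = pl$cache))
  }

  br_s <- run_branch(batch$X_seq, params$conv_seq_W, params$conv_seq_b,
                     cfg$kernel_widths[1L])
  cc$seq <- br_s$cache
  if (has_structure_branch(cfg)) {
    if (is.null(batch$X_struct))
      abort("kmerbind_missing_structure",
            "variant '%s' requires structure input", cfg$variant)
    if (dim(batch$X_struct)[3L] != cfg$input_dim_struct)
      abort("kmerbind_dimension_error", "structure feature dimension %d != configured %d",
            dim(batch$X_struct)[3L], cfg$input_dim_struct)
    br_t <- run_branch(batch$X_struct, params$conv_struct_W, params$conv_struct_b,
                       cfg$kernel_widths[2L])
    cc$struct <- br_t$cache
    dims <- dim(br_s$out)
    J <- array(0, c(dims[1L], dims[2L], 2L * dims[3L]))
    J[, , seq_len(dims[3L])] <- br_s$out
    J[, , dims[3L] + seq_len(dims[3L])] <- br_t$out
  } else {
    J <- br_s$out
  }
  lens1 <- br_s$lens
  cc$Fo <- dim(br_s$out)[3L]

  cv_j <- conv1d_forward(J, params$conv_joint_W, params$conv_joint_b,
                         cfg$kernel_widths[3L])
  relu_j <- cv_j$out > 0
  Aj <- cv_j$out * relu_j
  Aj <- mask_positions(Aj, lens1)
  if (any(lens1 < pw))
    abort("kmerbind_dimension_error", "sequence too short after first pooling")
  pl_j <- maxpool_forward(Aj, lens1, pw)
  cc$joint <- list(conv = cv_j$cache, relu = relu_j, pool = pl_j$cache)
  lens2 <- pl_j$lens
  cc$lens2 <- lens2

  gm_conv <- globalmax_forward(pl_j$out, lens2)
  cc$gmax_conv <- gm_conv$cache
  if (cfg$variant == "cnn_only") {
    feat <- gm_conv$out
  } else {
    # bidirectional LSTM over the pooled feature sequence; the per-position
    # hidden states of the two directions are concatenated (64 features for
    # 32 units per direction), max-pooled over valid positions, and joined
    # with the max-pooled convolution features entering the dense layers
    fwd <- lstm_forward(pl_j$out, lens2, params$lstm_f_Wx, params$lstm_f_Wh,
                        params$lstm_f_b)
    Xr <- reverse_batch(pl_j$out, lens2)
    bwd <- lstm_forward(Xr, lens2, params$lstm_b_Wx, params$lstm_b_Wh,
                        params$lstm_b_b)
    u <- cfg$lstm_units
    dims2 <- dim(fwd$hseq)
    Hb_al <- reverse_batch(bwd$hseq, lens2)   # align backward states to positions
    Hcat <- array(0, c(dims2[1L], dims2[2L], 2L * u))
    Hcat[, , seq_len(u)] <- fwd$hseq
    Hcat[, , u + seq_len(u)] <- Hb_al
    gm <- globalmax_forward(Hcat, lens2)
    feat <- cbind(gm_conv$out, gm$out)
    cc$lstm_f <- fwd$cache; cc$lstm_b <- bwd$cache; cc$gmax <- gm$cache
  }

  if (training && (cfg$dropout > 0 || cfg$recurrent_dropout > 0)) {
    # inverted dropout; the recurrent feature block gets its own (heavier) rate
    rate <- matrix(cfg$dropout, nrow(feat), ncol(feat))
    if (cfg$variant != "cnn_only" && cfg$recurrent_dropout > 0)
      rate[, (cc$Fo + 1L):ncol(feat)] <- cfg$recurrent_dropout
    keep <- matrix(runif(length(feat)), nrow(feat), ncol(feat)) >= rate
    drop_mask <- keep / (1 - rate)
    feat <- feat * drop_mask
    cc$dropout <- drop_mask
  }

  d1 <- dense_forward(feat, params$fc1_W, params$fc1_b)
  relu1 <- d1$out > 0
  A1 <- d1$out * relu1
  d2 <- dense_forward(A1, params$fc2_W, params$fc2_b)
  logit <- drop(d2$out)
  cc$fc1 <- d1$cache; cc$relu1 <- relu1; cc$fc2 <- d2$cache
  list(p = sigmoid(logit), logit = logit, cache = cc)
}

# dlogit: (B) gradient of the loss w.r.t. the pre-sigmoid output.
#' @keywords internal
#' @noRd
network_backward <- function(params, cfg, cache, dlogit) {
  g <- list()
  b2 <- dense_backward(cache$fc2, matrix(dlogit, ncol = 1L))
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  dA1 <- b2$dX * cache$relu1
  b1 <- dense_backward(cache$fc1, dA1)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dfeat <- b1$dX
  if (!is.null(cache$dropout)) dfeat <- dfeat * cache$dropout

  if (cfg$variant == "cnn_only") {
    dJp <- globalmax_backward(cache$gmax_conv, dfeat)
  } else {
    u <- cfg$lstm_units
    Fo <- cache$Fo
    dJp <- globalmax_backward(cache$gmax_conv, dfeat[, seq_len(Fo), drop = FALSE])
    dHcat <- globalmax_backward(cache$gmax, dfeat[, Fo + seq_len(2L * u), drop = FALSE])
    dHf <- dHcat[, , seq_len(u), drop = FALSE]
    dHb <- reverse_batch(dHcat[, , u + seq_len(u), drop = FALSE], cache$lens2)
    bf <- lstm_backward(cache$lstm_f, dHseq = dHf)
    bb <- lstm_backward(cache$lstm_b, dHseq = dHb)
    g$lstm_f_Wx <- bf$dWx; g$lstm_f_Wh <- bf$dWh; g$lstm_f_b <- bf$db
    g$lstm_b_Wx <- bb$dWx; g$lstm_b_Wh <- bb$dWh; g$lstm_b_b <- bb$db
    dJp <- dJp + bf$dX + reverse_batch(bb$dX, cache$lens2)
  }

  dAj <- maxpool_backward(cache$joint$pool, dJp)
  dCj <- dAj * cache$joint$relu
  bj <- conv1d_backward(cache$joint$conv, dCj)
  g$conv_joint_W <- bj$dW; g$conv_joint_b <- bj$db
  dJ <- bj$dX

  back_branch <- function(br_cache, dOut) {
    dA <- maxpool_backward(br_cache$pool, dOut)
    dC <- dA * br_cache$relu
    conv1d_backward(br_cache$conv, dC)
  }
  Fo <- cache$Fo
  if (has_structure_branch(cfg)) {
    bs <- back_branch(cache$seq, dJ[, , seq_len(Fo), drop = FALSE])
    bt <- back_branch(cache$struct, dJ[, , Fo + seq_len(Fo), drop = FALSE])
    g$conv_struct_W <- bt$dW; g$conv_struct_b <- bt$db
  } else {
    bs <- back_branch(cache$seq, dJ)
  }
  g$conv_seq_W <- bs$dW; g$conv_seq_b <- bs$db
  g
}

#' Forward pass: binding probabilities for a prepared batch
#'
#' @param model A `kmerbind_model` (from [build_model()] or [train_model()]).
#' @param batch List with `X_seq` (`(T,B,d)` array), optional `X_struct`, and
#'   `lens` (true token counts). See [prepare_batch()].
#' @return Numeric vector of probabilities in (0, 1), one per example.
#' @export
model_forward <- function(model, batch) {
  network_forward(model$params, model$config, batch, training = FALSE)$p
}

# Binary cross-entropy loss and parameter gradients on one batch.
#' @keywords internal
#' @noRd
network_loss_grads <- function(params, cfg, batch, y, training = FALSE) {
  fw <- network_forward(params, cfg, batch, training = training)
  p <- fw$p
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dlogit <- (p - y) / length(y)
  grads <- network_backward(params, cfg, fw$cache, dlogit)
  list(loss = loss, grads = grads, p = p)
}
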
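# Native neural-network primitives: 1-D convolution (zero-padded, 'same'
# length), masked max-pooling, a masked LSTM with full backpropagation through
# time, dense layers, and Adam. Batches are stored as 3-D arrays with
# dimensions (time, batch, channel) so that a time-slice reshapes to a
# (time*batch) x channel matrix without copying semantics getting in the way;
# all heavy lifting is GEMM via im2col.
#
# Every forward returns a cache consumed by the matching backward; gradients
# are exact (verified against central differences in the test suite).

# ---- convolution -----------------------------------------------------------

# X: (T, B, C); W: (w*C, F) with offset-major blocks; b: (F).
# 'same' zero padding: output position t reads input t-p_l .. t+p_r,
# p_l = floor((w-1)/2). Padding with zeros means positions inside each
# example's true length are unaffected by how far the batch is padded.
#' @keywords internal
#' @noRd
conv1d_forward <- function(X, W, b, w) {
  dims <- dim(X); Tt <- dims[1L]; B <- dims[2L]; C <- dims[3L]
  Fo <- length(b)
  p_l <- (w - 1L) %/% 2L
  Xpad <- array(0, c(Tt + w - 1L, B, C))
  Xpad[(p_l + 1L):(p_l + Tt), , ] <- X
  M <- matrix(0, Tt * B, w * C)
  for (o in seq_len(w)) {
    blk <- Xpad[o:(o + Tt - 1L), , , drop = FALSE]
    M[, ((o - 1L) * C + 1L):(o * C)] <- matrix(blk, Tt * B, C)
  }
  Y <- M %*% W
  Y <- Y + rep(b, each = Tt * B)
  list(out = array(Y, c(Tt, B, Fo)), cache = list(M = M, W = W, dims = dims, w = w))
}

#' @keywords internal
#' @noRd
conv1d_backward <- function(cache, dY) {
  dims <- cache$dims; Tt <- dims[1L]; B <- dims[2L]; C <- dims[3L]
  w <- cache$w
  dY_mat <- matrix(dY, Tt * B, dim(dY)[3L])
  dW <- crossprod(cache$M, dY_mat)
  db <- colSums(dY_mat)
  dM <- dY_mat %*% t(cache$W)
  p_l <- (w - 1L) %/% 2L
  dXpad <- array(0, c(Tt + w - 1L, B, C))
  for (o in seq_len(w)) {
    blk <- array(dM[, ((o - 1L) * C + 1L):(o * C)], c(Tt, B, C))
    dXpad[o:(o + Tt - 1L), , ] <- dXpad[o:(o + Tt - 1L), , , drop = FALSE] + blk
  }
  list(dX = dXpad[(p_l + 1L):(p_l + Tt), , , drop = FALSE], dW = dW, db = db)
}

# ---- masking ---------------------------------------------------------------

# Zero positions t > lens[b]. X: (T,B,C); lens: length-B integer.
#' @keywords internal
#' @noRd
mask_positions <- function(X, lens) {
  Tt <- dim(X)[1L]; B <- dim(X)[2L]
  m <- outer(seq_len(Tt), lens, `<=`)        # (T,B) 1/0
  X * as.vector(m)                           # recycles (T*B) over channels
}

# ---- max pooling -----------------------------------------------------------

# Non-overlapping windows of width pw along time. Output length floor(T/pw);
# per-example valid length becomes floor(len/pw). Assumes X already masked.
#' @keywords internal
#' @noRd
maxpool_forward <- function(X, lens, pw) {
  dims <- dim(X); Tt <- dims[1L]; B <- dims[2L]; Fo <- dims[3L]
  T2 <- Tt %/% pw
  if (T2 == 0L) abort("kmerbind_dimension_error",
                      "pooling window %d exceeds sequence length %d", pw, Tt)
  Tr <- T2 * pw
  out <- X[seq(1L, Tr, by = pw), , , drop = FALSE]
  arg <- array(1L, c(T2, B, Fo))
  if (pw > 1L) for (o in 2L:pw) {
    cand <- X[seq(o, Tr, by = pw), , , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- o
  }
  lens2 <- lens %/% pw
  out <- mask_positions(out, lens2)
  list(out = out, lens = lens2,
       cache = list(arg = arg, dims = dims, pw = pw, lens2 = lens2))
}

#' @keywords internal
#' @noRd
maxpool_backward <- function(cache, dY) {
  dims <- cache$dims; Tt <- dims[1L]; B <- dims[2L]; Fo <- dims[3L]
  pw <- cache$pw
  T2 <- Tt %/% pw
  dY <- mask_positions(dY, cache$lens2)      # masked outputs carry no gradient
  t2_arr <- array(seq_len(T2), c(T2, B, Fo))
  b_arr <- array(rep(seq_len(B), each = T2), c(T2, B, Fo))
  f_arr <- array(rep(seq_len(Fo), each = T2 * B), c(T2, B, Fo))
  lin <- ((f_arr - 1L) * B + (b_arr - 1L)) * Tt + (t2_arr - 1L) * pw + cache$arg
  dX <- array(0, c(Tt, B, Fo))
  dX[as.vector(lin)] <- as.vector(dY)
  dX
}

# Global max over valid time positions per channel (used by the CNN-only
# variant in place of the recurrent layer). Returns (B, F).
#' @keywords internal
#' @noRd
globalmax_forward <- function(X, lens) {
  dims <- dim(X); Tt <- dims[1L]; B <- dims[2L]; Fo <- dims[3L]
  neg <- -Inf
  m <- outer(seq_len(Tt), lens, `>`)
  Xm <- X
  Xm[array(as.vector(m), dims)] <- neg
  out <- apply(Xm, c(2L, 3L), max)
  arg <- apply(Xm, c(2L, 3L), which.max)
  list(out = out, cache = list(arg = arg, dims = dims))
}

#' @keywords internal
#' @noRd
globalmax_backward <- function(cache, dY) {
  dims <- cache$dims; Tt <- dims[1L]; B <- dims[2L]; Fo <- dims[3L]
  b_arr <- matrix(rep(seq_len(B), times = Fo), B, Fo)
  f_arr <- matrix(rep(seq_len(Fo), each = B), B, Fo)
  lin <- ((f_arr - 1L) * B + (b_arr - 1L)) * Tt + cache$arg
  dX <- array(0, dims)
  dX[as.vector(lin)] <- as.vector(dY)
  dX
}

# ---- LSTM ------------------------------------------------------------------

# Masked unidirectional LSTM. X: (T, B, Cin); lens: valid steps per example.
# Gate layout in the fused weight matrices: [forget | input | candidate | output].
# For steps beyond an example's length the state is carried through unchanged,
# so the final state equals the state at the example's last valid step.
#' @keywords internal
#' @noRd
lstm_forward <- function(X, lens, Wx, Wh, b) {
  dims <- dim(X); Tt <- dims[1L]; B <- dims[2L]; Cin <- dims[3L]
  u <- nrow(Wh)
  H <- matrix(0, B, u); Cs <- matrix(0, B, u)
  Hseq <- array(0, c(Tt, B, u))
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    x <- matrix(X[t, , ], B, Cin)
    z <- x %*% Wx + H %*% Wh
    z <- sweep(z, 2L, b, `+`)
    f <- sigmoid(z[, 1:u, drop = FALSE])
    i <- sigmoid(z[, (u + 1L):(2L * u), drop = FALSE])
    g <- tanh(z[, (2L * u + 1L):(3L * u), drop = FALSE])
    o <- sigmoid(z[, (3L * u + 1L):(4L * u), drop = FALSE])
    Cnew <- f * Cs + i * g
    Hnew <- o * tanh(Cnew)
    act <- as.numeric(lens >= t)
    steps[[t]] <- list(x = x, f = f, i = i, g = g, o = o,
                       Cprev = Cs, Hprev = H, Cnew = Cnew, act = act)
    Cs <- act * Cnew + (1 - act) * Cs
    H <- act * Hnew + (1 - act) * H
    Hseq[t, , ] <- H
  }
  list(h = H, hseq = Hseq, cache = list(steps = steps, dims = dims, u = u,
                                        Wx = Wx, Wh = Wh))
}

# Gradient entry points: dH_final (B, u) w.r.t. the final hidden state, and/or
# dHseq (T, B, u) w.r.t. the per-step output states.
#' @keywords internal
#' @noRd
lstm_backward <- function(cache, dH_final = NULL, dHseq = NULL) {
  dims <- cache$dims; Tt <- dims[1L]; B <- dims[2L]; Cin <- dims[3L]
  u <- cache$u; Wx <- cache$Wx; Wh <- cache$Wh
  dWx <- matrix(0, Cin, 4L * u); dWh <- matrix(0, u, 4L * u); db <- numeric(4L * u)
  dX <- array(0, dims)
  dH <- if (is.null(dH_final)) matrix(0, B, u) else dH_final
  dC <- matrix(0, B, u)
  for (t in rev(seq_len(Tt))) {
    if (!is.null(dHseq)) dH <- dH + matrix(dHseq[t, , ], B, u)
    st <- cache$steps[[t]]
    act <- st$act
    dHa <- act * dH                        # gradient reaching Hnew (active rows)
    dCa <- act * dC
    tc <- tanh(st$Cnew)
    do_ <- dHa * tc
    dCt <- dCa + dHa * st$o * (1 - tc^2)
    df <- dCt * st$Cprev
    di <- dCt * st$g
    dg <- dCt * st$i
    dz <- cbind(df * st$f * (1 - st$f),
                di * st$i * (1 - st$i),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$x, dz)
    dWh <- dWh + crossprod(st$Hprev, dz)
    db <- db + colSums(dz)
    dX[t, , ] <- dz %*% t(Wx)
    dH_gates <- dz %*% t(Wh)
    dH <- dH_gates + (1 - act) * dH
    dC <- dCt * st$f + (1 - act) * dC
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# Reverse each example's valid prefix along time (positions past the length
# stay zero), used to run the backward direction of the BiLSTM.
#' @keywords internal
#' @noRd
reverse_batch <- function(X, lens) {
  out <- array(0, dim(X))
  for (b in seq_along(lens)) {
    L <- lens[b]
    if (L > 0L) out[1:L, b, ] <- X[L:1, b, , drop = FALSE]
  }
  out
}

# ---- dense -----------------------------------------------------------------

#' @keywords internal
#' @noRd
dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, `+`), cache = list(X = X, W = W))
}

#' @keywords internal
#' @noRd
dense_backward <- function(cache, dY) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- parameter initialization & Adam ---------------------------------------

#' @keywords internal
#' @noRd
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' @keywords internal
#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay applies to weight matrices only (names ending _W,
# _Wx, _Wh), never biases.
#' @keywords internal
#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && grepl("_W(x|h)?$", nm)) p <- p * (1 - lr * weight_decay)
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

# Branch scale equalization: shape strings are long runs of one k-mer, so the
# structure convolution sums coherently and its output is several-fold larger
# than the sequence branch's, drowning the sequence signal in the joint
# module. Rescale the structure convolution once, on a reference batch, so
# its masked output standard deviation matches the sequence branch's.
# Deterministic given the batch; a no-op for variants without the branch.
#' @keywords internal
#' @noRd
calibrate_conv_scales <- function(params, cfg, batch) {
  if (!has_structure_branch(cfg)) return(params)
  lens0 <- batch$lens
  branch_sd <- function(X, W, b, w) {
    cv <- conv1d_forward(X, W, b, w)
    stats::sd(mask_positions(cv$out, lens0))
  }
  s_seq <- branch_sd(batch$X_seq, params$conv_seq_W, params$conv_seq_b,
                     cfg$kernel_widths[1L])
  s_str <- branch_sd(batch$X_struct, params$conv_struct_W, params$conv_struct_b,
                     cfg$kernel_widths[2L])
  if (is.finite(s_seq) && is.finite(s_str) && s_str > 1e-8 && s_seq > 1e-8) {
    r <- s_seq / s_str
    params$conv_struct_W <- params$conv_struct_W * r
    params$conv_struct_b <- params$conv_struct_b * r
  }
  params
}
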
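# Dataset splitting, classifier training with early stopping on validation
# AUC, prediction, the rank-based AUC itself, and the ablation grid that
# contrasts the full model with its reduced variants (no structure branch /
# one-hot encoding / CNN without the recurrent layer).

#' Training configuration
#'
#' Optimization uses Adam on binary cross-entropy. Early stopping watches
#' validation AUC (the evaluation metric) with the given patience, and the
#' best-validation weights are restored at the end.
#'
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Examples per minibatch (default 128).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Epochs without validation-AUC improvement before stopping;
#'   0 disables early stopping.
#' @param weight_decay Decoupled L2 decay applied to weight matrices (not
#'   biases) at every Adam step.
#' @param calibrate Rescale each convolution once, on a reference batch, so
#'   its pre-activation standard deviation is ~1 before training (corrects the
#'   scale imbalance between the decorrelated sequence inputs and the highly
#'   repetitive shape inputs).
#' @param seed RNG seed for shuffling, dropout and any stochastic step.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 128L, lr = 1e-3,
                         patience = 5L, weight_decay = 1e-4, calibrate = TRUE,
                         seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, patience >= 0L,
            weight_decay >= 0, is.logical(calibrate))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, patience = as.integer(patience),
                 weight_decay = weight_decay, calibrate = calibrate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation(/test) split
#'
#' Partitions a labeled dataset stratified by label: first `test_fraction` of
#' each class is held out as the test set, then `val_fraction` of the
#' remainder becomes the validation set (the conventional choice is one third
#' for validation, two thirds for training).
#'
#' @param ds A `labeled_dataset`.
#' @param val_fraction Fraction of the non-test data used for validation.
#' @param test_fraction Fraction held out as the test partition (0 when an
#'   external test set is supplied separately).
#' @param seed RNG seed; the same seed always yields the same partitions.
#' @return List with `train`, `validation`, `test` (`labeled_dataset`s; `test`
#'   may be empty) and `seed`.
#' @export
split_dataset <- function(ds, val_fraction = 1 / 3, test_fraction = 0, seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, test_fraction >= 0, test_fraction < 1)
  tab <- table(ds$label)
  if (length(tab) < 2L || any(tab < 2L))
    abort("kmerbind_stratification_error",
          "each label class needs at least 2 examples (got %s)",
          paste(sprintf("%s:%d", names(tab), tab), collapse = ", "))
  with_seed(seed, {
    te <- va <- integer(0)
    for (lab in unique(ds$label)) {
      idx <- sample(which(ds$label == lab))
      n_te <- round(length(idx) * test_fraction)
      te <- c(te, idx[seq_len(n_te)])
      rest <- if (n_te > 0L) idx[-seq_len(n_te)] else idx
      n_va <- round(length(rest) * val_fraction)
      va <- c(va, rest[seq_len(n_va)])
    }
    tr <- setdiff(seq_along(ds$label), c(te, va))
    list(train = ds[sort(tr)], validation = ds[sort(va)], test = ds[sort(te)],
         seed = as.integer(seed))
  })
}

#' One-hot encode a normalized RNA sequence
#'
#' Identity code, one row per nucleotide: A=(1,0,0,0), C=(0,1,0,0),
#' G=(0,0,1,0), U=(0,0,0,1).
#'
#' @param seq Residue string over `{A,C,G,U}`.
#' @return An `L x 4` matrix with columns A, C, G, U.
#' @export
one_hot_encode <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(ch, RNA_ALPHABET)
  if (anyNA(idx))
    abort("kmerbind_alphabet_error", "foreign character '%s' at position %d",
          ch[which(is.na(idx))[1L]], which(is.na(idx))[1L])
  m <- matrix(0, length(ch), 4L, dimnames = list(NULL, RNA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a one-hot matrix back to a residue string
#'
#' @param m Matrix from [one_hot_encode()].
#' @return Residue string.
#' @export
one_hot_decode <- function(m) {
  paste(RNA_ALPHABET[max.col(m)], collapse = "")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes `P(score+ > score-) + 0.5 P(tie)` via midranks, which equals the
#' trapezoidal area under the ROC curve, and is invariant to strictly
#' monotone transforms of the scores.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher meaning more likely positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' compute_auc(c(1, 0, 1, 0), c(.9, .8, .7, .1))  # 0.75: 3 of 4 pairs ordered
#' @export
compute_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    abort("kmerbind_undefined_auc", "AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- feature preparation ---------------------------------------------------

# Turn dataset examples into per-example feature matrices according to the
# model variant. Returns list(seq = list of T x d matrices,
# struct = list or NULL).
#' @keywords internal
#' @noRd
featurize_examples <- function(ds, embeddings, cfg) {
  if (cfg$variant == "one_hot") {
    return(list(seq = lapply(ds$sequence, one_hot_encode), struct = NULL))
  }
  seq_m <- lapply(ds$sequence, function(s)
    embed_tokens(tokenize(s, embeddings$seq$vocab), embeddings$seq))
  struct_m <- NULL
  if (cfg$variant %in% c("full", "cnn_only")) {
    if (any(is.na(ds$shape)))
      abort("kmerbind_missing_structure",
            "variant '%s' requires shape strings for every example", cfg$variant)
    if (is.null(embeddings$struct))
      abort("kmerbind_missing_structure", "no structure embedding supplied")
    struct_m <- lapply(ds$shape, function(s)
      embed_tokens(tokenize(s, embeddings$struct$vocab), embeddings$struct))
  }
  list(seq = seq_m, struct = struct_m)
}

#' Assemble a padded batch for the network from feature matrices
#'
#' @param feats Result of the internal featurizer: list with `seq` (list of
#'   matrices) and optional `struct`.
#' @param idx Indices of the examples to include.
#' @return Batch list (`X_seq`, `X_struct`, `lens`) for [model_forward()].
#' @keywords internal
#' @noRd
assemble_batch <- function(feats, idx) {
  pm <- pad_and_mask(feats$seq[idx])
  batch <- list(X_seq = pm$X, X_struct = NULL, lens = pm$lens)
  if (!is.null(feats$struct)) {
    Tm <- dim(pm$X)[1L]
    d2 <- ncol(feats$struct[[idx[1L]]])
    Xs <- array(0, c(Tm, length(idx), d2))
    for (b in seq_along(idx)) {
      m <- feats$struct[[idx[b]]]
      Xs[seq_len(nrow(m)), b, ] <- m
    }
    batch$X_struct <- Xs
  }
  batch
}

#' Center and rescale an embedding for downstream use
#'
#' Subtracts the vocabulary-mean vector from every input vector and rescales
#' so the mean row norm is 1. Skip-gram solutions carry a large shared
#' component common to all tokens (on low-information corpora it can dominate
#' the vectors); removing it and fixing the scale leaves the relational
#' structure intact while giving the classifier a well-conditioned input.
#'
#' @param emb A `kmer_embedding`.
#' @return The embedding with conditioned `input_vectors`.
#' @export
condition_embedding <- function(emb) {
  U <- emb$input_vectors
  U <- sweep(U, 2L, colMeans(U))
  nrm <- mean(sqrt(rowSums(U^2)))
  if (nrm > 0) U <- U / nrm
  emb$input_vectors <- U
  emb
}

#' Train skip-gram embeddings for a dataset's sequences and shape strings
#'
#' Two independent skip-gram models are fitted (the sequence and structure
#' vocabularies are disjoint). By default the corpus is the supplied dataset —
#' pass the training split to avoid test leakage. The returned input vectors
#' are conditioned with [condition_embedding()].
#'
#' @param ds A `labeled_dataset`.
#' @param cfg_seq,cfg_struct [skipgram_config()]s for the two models.
#' @param structure_alphabet Shape alphabet; default the six loop-type letters.
#'   Supplying five letters reproduces a 125-k-mer structure vocabulary.
#' @param k k-mer size.
#' @return List with `seq` and (when shapes are present) `struct`
#'   `kmer_embedding`s.
#' @export
train_embeddings <- function(ds, cfg_seq = skipgram_config(),
                             cfg_struct = skipgram_config(),
                             structure_alphabet = SHAPE_ALPHABET, k = 3L) {
  vocab_seq <- build_vocabulary(RNA_ALPHABET, k)
  corpus_seq <- lapply(ds$sequence, tokenize, vocab = vocab_seq)
  out <- list(seq = condition_embedding(train_skipgram(corpus_seq, vocab_seq, cfg_seq)))
  if (!all(is.na(ds$shape))) {
    vocab_st <- build_vocabulary(structure_alphabet, k)
    corpus_st <- lapply(ds$shape[!is.na(ds$shape)], tokenize, vocab = vocab_st)
    out$struct <- condition_embedding(train_skipgram(corpus_st, vocab_st, cfg_struct))
  }
  out
}

#' Train the binding-site classifier
#'
#' Minimizes binary cross-entropy with Adam; after every epoch the validation
#' AUC is computed and early stopping (patience) applies; the weights of the
#' best validation epoch are restored. Embedding matrices are frozen.
#'
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param splits A [split_dataset()] result (the `test` partition is unused
#'   here).
#' @param embeddings A [train_embeddings()] result (ignored by the `one_hot`
#'   variant).
#' @return A `kmerbind_model` with an added `history` data frame (epoch,
#'   train_loss, val_auc) and `best_epoch`.
#' @export
train_model <- function(cfg, tcfg, splits, embeddings = NULL) {
  stopifnot(inherits(cfg, "model_config"), inherits(tcfg, "train_config"))
  tr <- splits$train; va <- splits$validation
  if (length(tr) == 0L || length(unique(tr$label)) < 2L)
    abort("kmerbind_invalid_input", "degenerate training split")
  feats_tr <- featurize_examples(tr, embeddings, cfg)
  feats_va <- featurize_examples(va, embeddings, cfg)
  model <- build_model(cfg)
  params <- model$params
  if (isTRUE(tcfg$calibrate)) {
    # one-time conv scale calibration on a reference batch (see nn.R)
    params <- calibrate_conv_scales(params, cfg,
                                    assemble_batch(feats_tr, seq_len(min(64L, length(tr)))))
  }
  y_tr <- tr$label
  n <- length(tr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  with_seed(tcfg$seed, {
    adam <- adam_init(params)
    stale <- 0L
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        batch <- assemble_batch(feats_tr, idx)
        lg <- network_loss_grads(params, cfg, batch, y_tr[idx], training = TRUE)
        upd <- adam_step(params, lg$grads, adam, lr = tcfg$lr,
                         weight_decay = tcfg$weight_decay)
        params <- upd$params; adam <- upd$state
        losses <- c(losses, lg$loss)
      }
      scores_va <- predict_scores(params, cfg, feats_va, tcfg$batch_size)
      val_auc <- compute_auc(va$label, scores_va)
      history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                           val_auc = val_auc))
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (tcfg$patience > 0L && stale >= tcfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$train_config <- tcfg
  model
}

# Batched forward pass over pre-featurized examples.
#' @keywords internal
#' @noRd
predict_scores <- function(params, cfg, feats, batch_size = 128L) {
  n <- length(feats$seq)
  scores <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- assemble_batch(feats, idx)
    scores[idx] <- network_forward(params, cfg, batch, training = FALSE)$p
  }
  scores
}

#' Score a labeled dataset with a trained model
#'
#' @param model A trained `kmerbind_model`.
#' @param ds A `labeled_dataset`.
#' @param embeddings The embeddings used at training time.
#' @param batch_size Examples per forward batch.
#' @return Data frame with `id`, `label`, `score` (order preserved).
#' @export
predict_dataset <- function(model, ds, embeddings = NULL, batch_size = 128L) {
  feats <- featurize_examples(ds, embeddings, model$config)
  data.frame(id = ds$id, label = ds$label,
             score = predict_scores(model$params, model$config, feats, batch_size),
             stringsAsFactors = FALSE)
}

#' Train and evaluate a grid of model variants under shared seeds
#'
#' All variants use identical data splits, identical skip-gram embeddings
#' (where applicable) and identical seeds, so differences in test AUC are
#' attributable to the architectural change alone.
#'
#' @param ds A `labeled_dataset` (shapes required if `full`/`cnn_only` is
#'   requested).
#' @param variants Subset of `full`, `no_structure`, `one_hot`, `cnn_only`.
#' @param base_cfg Template [model_config()]; the variant field is overridden
#'   per run.
#' @param tcfg Shared [train_config()].
#' @param sg_cfg Shared [skipgram_config()] for both embedding models.
#' @param val_fraction,test_fraction Passed to [split_dataset()].
#' @param seed Split seed.
#' @return List of evaluation reports (one per variant: `variant`, `auc`,
#'   `per_example`), with a summary data frame attached as attribute
#'   `"summary"` and printed by `summary_ablation`.
#' @export
run_ablation <- function(ds, variants = MODEL_VARIANTS,
                         base_cfg = model_config(), tcfg = train_config(),
                         sg_cfg = skipgram_config(),
                         val_fraction = 1 / 3, test_fraction = 0.25, seed = 1L) {
  variants <- match.arg(variants, MODEL_VARIANTS, several.ok = TRUE)
  if (any(variants %in% c("full", "cnn_only")) && all(is.na(ds$shape)))
    abort("kmerbind_missing_structure",
          "variants %s need shape strings",
          paste(intersect(variants, c("full", "cnn_only")), collapse = ", "))
  splits <- split_dataset(ds, val_fraction, test_fraction, seed)
  if (length(splits$test) == 0L)
    abort("kmerbind_invalid_input", "ablation needs a non-empty test partition")
  sg_struct <- sg_cfg; sg_struct$seed <- sg_cfg$seed + 1L
  embeddings <- train_embeddings(splits$train, sg_cfg, sg_struct)
  base_cfg$input_dim_seq <- sg_cfg$dim
  base_cfg$input_dim_struct <- sg_cfg$dim
  reports <- lapply(variants, function(v) {
    cfg <- base_cfg
    cfg$variant <- v
    if (v == "one_hot") cfg$input_dim_seq <- 4L
    model <- train_model(cfg, tcfg, splits, embeddings)
    pred <- predict_dataset(model, splits$test, embeddings, tcfg$batch_size)
    list(variant = v, auc = compute_auc(pred$label, pred$score),
         per_example = pred, best_epoch = model$best_epoch)
  })
  names(reports) <- variants
  attr(reports, "summary") <- data.frame(
    variant = variants,
    test_auc = vapply(reports, `[[`, numeric(1L), "auc"),
    best_epoch = vapply(reports, `[[`, integer(1L), "best_epoch"),
    row.names = NULL)
  class(reports) <- "ablation_result"
  reports
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Ablation results (shared splits, embeddings and seeds):\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
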
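# Distributed representation of k-mers. Sequences and shape strings are split
# into overlapping k-mers (stride 1) and a skip-gram model with negative
# sampling learns a dense d-dimensional vector per k-mer:
#
#   maximize  log sigma(w_o . u_c) + sum_{i=1..n_neg} E_{s_i ~ Pn}[log sigma(-w_{s_i} . u_c)]
#
# where u are the input ("center") vectors, w the output ("context") vectors,
# and Pn the unigram distribution raised to `noise_power` and renormalized.
# The input vectors are the downstream representation.

#' Build a complete k-mer vocabulary
#'
#' Enumerates all `|alphabet|^k` k-mers in lexicographic order (alphabet order
#' as given), so indices are stable across runs and machines. The vocabulary is
#' the full enumeration, not corpus-derived: k-mers never seen in a corpus
#' still have (untrained) rows in the embedding.
#'
#' @param alphabet Character vector of single symbols, e.g. `c("A","C","G","U")`.
#' @param k k-mer length (default 3).
#' @return A `kmer_vocabulary`: list with `k`, `alphabet`, `kmers` (character,
#'   position i is the k-mer with index i) and `V`.
#' @examples
#' build_vocabulary(c("A", "C", "G", "U"), 3)$V   # 64
#' build_vocabulary(c("S", "M", "H", "I", "T"), 3)$V  # 125
#' @export
build_vocabulary <- function(alphabet, k = 3L) {
  if (length(alphabet) == 0L || any(nchar(alphabet) != 1L) || anyDuplicated(alphabet))
    abort("kmerbind_invalid_input", "alphabet must be distinct single characters")
  if (k < 1L) abort("kmerbind_invalid_input", "k must be >= 1")
  g <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  kmers <- do.call(paste0, rev(g))   # last position varies fastest => lexicographic
  structure(list(k = as.integer(k), alphabet = alphabet, kmers = kmers,
                 V = length(kmers)),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat(sprintf("<kmer_vocabulary> k=%d over {%s}: V=%d\n",
              x$k, paste(x$alphabet, collapse = ","), x$V))
  invisible(x)
}

#' Tokenize a string into overlapping k-mer indices
#'
#' Sliding window of width k, stride 1: a string of length L yields L-k+1
#' tokens. Indices are 1-based positions in the vocabulary enumeration.
#'
#' @param s Residue or shape string.
#' @param vocab A [build_vocabulary()] result.
#' @return Integer vector of token indices in `[1, V]`.
#' @examples
#' v <- build_vocabulary(c("A","C","G","U"), 3)
#' v$kmers[tokenize("AUUGC", v)]   # "AUU" "UUG" "UGC"
#' @export
tokenize <- function(s, vocab) {
  k <- vocab$k
  L <- nchar(s)
  if (L < k)
    abort("kmerbind_too_short", "string of length %d is shorter than k = %d", L, k)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  idx <- match(kmers, vocab$kmers)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort("kmerbind_alphabet_error",
          "k-mer '%s' at position %d is not in the vocabulary alphabet {%s}",
          kmers[bad], bad, paste(vocab$alphabet, collapse = ","))
  }
  idx
}

#' Enumerate skip-gram (center, context) training pairs
#'
#' For every position t and every offset j in `[-m, m]` except 0 that stays in
#' bounds, emits the ordered pair (token at t, token at t+j). Order is
#' deterministic: t ascending, then j ascending.
#'
#' @param tokens Integer token vector.
#' @param m Context window size (positions each side).
#' @return A 2-column integer matrix with columns `center`, `context`.
#' @export
skipgram_pairs <- function(tokens, m) {
  if (m < 1L) abort("kmerbind_invalid_input", "window m must be >= 1")
  n <- length(tokens)
  if (n < 2L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("center", "context"))))
  offs <- setdiff(seq(-m, m), 0L)
  t_rep <- rep(seq_len(n), each = length(offs))
  j_rep <- t_rep + rep(offs, times = n)
  keep <- j_rep >= 1L & j_rep <= n
  cbind(center = tokens[t_rep[keep]], context = tokens[j_rep[keep]])
}

#' Configuration for skip-gram training
#'
#' @param window Context window size m.
#' @param dim Embedding dimension d.
#' @param n_neg Negative samples per observed pair.
#' @param lr Initial learning rate (decays linearly over training).
#' @param epochs Passes over the pair set; 0 returns the initialization.
#' @param noise_power Exponent applied to the unigram counts to form the noise
#'   distribution (0.75 is the standard word2vec choice).
#' @param batch Pairs per mini-batch update.
#' @param clip Per-row cap on the norm of an aggregated gradient within one
#'   mini-batch. High-frequency k-mers (shape strings are runs of one token)
#'   can collect hundreds of coherent gradient terms per batch; without the
#'   cap those summed steps overshoot and diverge.
#' @param seed RNG seed; training is fully reproducible given this.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(window = 5L, dim = 30L, n_neg = 5L, lr = 0.025,
                            epochs = 10L, noise_power = 0.75, batch = 512L,
                            clip = 1, seed = 1L) {
  stopifnot(window >= 1L, dim >= 1L, n_neg >= 1L, lr > 0, epochs >= 0L,
            batch >= 1L, clip > 0)
  structure(list(window = as.integer(window), dim = as.integer(dim),
                 n_neg = as.integer(n_neg), lr = lr, epochs = as.integer(epochs),
                 noise_power = noise_power, batch = as.integer(batch),
                 clip = clip, seed = as.integer(seed)),
            class = "skipgram_config")
}

# Objective of one observed pair given center vector u (d), observed context
# vector w_pos (d), and sampled negative context vectors W_neg (n_neg x d).
#' @keywords internal
#' @noRd
sg_pair_objective <- function(u, w_pos, W_neg) {
  log(sigmoid(sum(w_pos * u))) + sum(log(sigmoid(-drop(W_neg %*% u))))
}

# Analytic gradient of sg_pair_objective. Returns list(du, dw_pos, dW_neg).
#' @keywords internal
#' @noRd
sg_pair_gradient <- function(u, w_pos, W_neg) {
  g_pos <- 1 - sigmoid(sum(w_pos * u))           # d log sigma(x) / dx
  s_neg <- sigmoid(drop(W_neg %*% u))            # -d log sigma(-x) / dx
  list(du = g_pos * w_pos - drop(crossprod(W_neg, s_neg)),
       dw_pos = g_pos * u,
       dW_neg = -outer(s_neg, u))
}

# Noise distribution over the vocabulary: unigram counts ^ power, renormalized.
#' @keywords internal
#' @noRd
sg_noise_distribution <- function(tokens_all, V, power) {
  counts <- tabulate(tokens_all, nbins = V)
  p <- counts^power
  if (sum(p) == 0) abort("kmerbind_empty_input", "empty corpus")
  p / sum(p)
}

#' Exact-expectation skip-gram objective over a pair set
#'
#' Evaluates the negative-sampling objective with the expectation over the
#' noise distribution taken exactly (summing over the vocabulary) instead of
#' sampled, so the value is deterministic. Used to monitor training progress.
#'
#' @param emb A `kmer_embedding`.
#' @param pairs 2-column (center, context) matrix.
#' @param noise Probability vector over the vocabulary.
#' @param n_neg Number of negative draws the objective budgets per pair.
#' @return Mean objective per pair (higher is better).
#' @export
skipgram_objective <- function(emb, pairs, noise, n_neg = 5L) {
  U <- emb$input_vectors; W <- emb$output_vectors
  dots <- rowSums(U[pairs[, 1L], , drop = FALSE] * W[pairs[, 2L], , drop = FALSE])
  pos_term <- log(sigmoid(dots))
  # E_{s~Pn} log sigma(-w_s . u_c) for every center in the batch
  S <- U[pairs[, 1L], , drop = FALSE] %*% t(W)   # n_pairs x V
  neg_term <- drop(log(sigmoid(-S)) %*% noise)
  mean(pos_term + n_neg * neg_term)
}

#' Train k-mer embeddings by skip-gram with negative sampling
#'
#' Maximizes the negative-sampling objective by mini-batch stochastic gradient
#' ascent over all (center, context) pairs from [skipgram_pairs()], with the
#' learning rate decaying linearly across updates. Negatives are drawn from
#' the unigram distribution raised to `noise_power`. Input vectors initialize
#' uniform in (-0.5/d, 0.5/d), output vectors at zero (the reference word2vec
#' scheme); rows of k-mers absent from the corpus are never updated.
#'
#' @param corpus List of integer token vectors (one per sequence).
#' @param vocab The [build_vocabulary()] vocabulary the tokens index into.
#' @param cfg A [skipgram_config()].
#' @return A `kmer_embedding`: list with `input_vectors` (V x d, the
#'   representation used downstream), `output_vectors` (V x d), `vocab`, `cfg`.
#' @export
train_skipgram <- function(corpus, vocab, cfg = skipgram_config()) {
  if (!length(corpus)) abort("kmerbind_empty_input", "empty corpus")
  toks_all <- unlist(corpus, use.names = FALSE)
  if (any(toks_all < 1L | toks_all > vocab$V))
    abort("kmerbind_index_error", "token index outside [1, V]")
  V <- vocab$V; d <- cfg$dim
  with_seed(cfg$seed, {
    U <- matrix(runif(V * d, -0.5 / d, 0.5 / d), V, d)
    W <- matrix(0, V, d)
    if (cfg$epochs > 0L) {
      pairs <- do.call(rbind, lapply(corpus, skipgram_pairs, m = cfg$window))
      if (nrow(pairs) == 0L)
        abort("kmerbind_empty_input", "corpus yields no skip-gram pairs")
      noise <- sg_noise_distribution(toks_all, V, cfg$noise_power)
      n_pairs <- nrow(pairs)
      n_chunks_total <- cfg$epochs * ceiling(n_pairs / cfg$batch)
      chunk_no <- 0L
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n_pairs)
        for (start in seq(1L, n_pairs, by = cfg$batch)) {
          idx <- ord[start:min(start + cfg$batch - 1L, n_pairs)]
          b <- length(idx)
          lr <- cfg$lr * max(1e-4, 1 - chunk_no / n_chunks_total)
          ctr <- pairs[idx, 1L]; ctx <- pairs[idx, 2L]
          neg <- sample.int(V, b * cfg$n_neg, replace = TRUE, prob = noise)
          Uc <- U[ctr, , drop = FALSE]; Wo <- W[ctx, , drop = FALSE]
          g_pos <- 1 - sigmoid(rowSums(Uc * Wo))            # b
          ctr_rep <- rep(ctr, times = cfg$n_neg)
          Ucr <- U[ctr_rep, , drop = FALSE]
          Wn <- W[neg, , drop = FALSE]
          s_neg <- sigmoid(rowSums(Ucr * Wn))               # b * n_neg
          # gradients (ascent direction), aggregated per distinct row index
          dU <- g_pos * Wo                                  # contribution from positives
          dU_neg <- (-s_neg) * Wn
          dW_pos <- g_pos * Uc
          dW_neg <- (-s_neg) * Ucr
          # mini-batch gradient: per-row sums of the per-pair gradients,
          # with each row's aggregated step clipped in norm so that
          # high-frequency k-mers do not overshoot
          upd_U <- rowsum(rbind(dU, dU_neg), c(ctr, ctr_rep))
          iU <- as.integer(rownames(upd_U))
          sc <- pmin(1, cfg$clip / sqrt(rowSums(upd_U^2) + 1e-12))
          U[iU, ] <- U[iU, ] + lr * (sc * upd_U)
          upd_W <- rowsum(rbind(dW_pos, dW_neg), c(ctx, neg))
          iW <- as.integer(rownames(upd_W))
          sc <- pmin(1, cfg$clip / sqrt(rowSums(upd_W^2) + 1e-12))
          W[iW, ] <- W[iW, ] + lr * (sc * upd_W)
          chunk_no <- chunk_no + 1L
        }
      }
    }
    structure(list(input_vectors = U, output_vectors = W, vocab = vocab,
                   cfg = cfg),
              class = "kmer_embedding")
  })
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat(sprintf("<kmer_embedding> V=%d, d=%d (k=%d over {%s})\n",
              x$vocab$V, ncol(x$input_vectors), x$vocab$k,
              paste(x$vocab$alphabet, collapse = ",")))
  invisible(x)
}

#' Look up embedding rows for a token sequence
#'
#' @param tokens Integer token vector.
#' @param emb A `kmer_embedding`.
#' @return A `length(tokens) x d` matrix; row i is the input vector of token i.
#' @export
embed_tokens <- function(tokens, emb) {
  V <- nrow(emb$input_vectors)
  if (length(tokens) && (min(tokens) < 1L || max(tokens) > V))
    abort("kmerbind_index_error", "token index outside [1, V]")
  emb$input_vectors[tokens, , drop = FALSE]
}

#' Write an embedding in word2vec text format
#'
#' Header line "V d", then one line per k-mer: the token followed by d floats.
#'
#' @param emb A `kmer_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_text <- function(emb, path) {
  U <- emb$input_vectors
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(U), ncol(U)), con)
  writeLines(paste(emb$vocab$kmers,
                   apply(U, 1L, function(r) paste(format(r, digits = 17), collapse = " "))),
             con)
  invisible(path)
}

#' Read a word2vec text-format embedding
#'
#' @param path Input path.
#' @return List with `kmers` (character) and `vectors` (V x d matrix).
#' @export
read_embedding_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  if (length(body) != hdr[1L])
    abort("kmerbind_parse_error", "embedding file row count != header V")
  kmers <- vapply(body, `[`, character(1L), 1L)
  vecs <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(hdr[2L])))
  list(kmers = kmers, vectors = vecs)
}
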
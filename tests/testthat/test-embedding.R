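test_that("vocabulary enumerates all k-mers with stable lexicographic indices", {
  v4 <- build_vocabulary(c("A", "C", "G", "U"), 3)
  expect_identical(v4$V, 64L)
  expect_identical(v4$kmers[1:5], c("AAA", "AAC", "AAG", "AAU", "ACA"))
  # bijection onto 1..V
  expect_identical(sort(match(v4$kmers, v4$kmers)), 1:64)
  expect_identical(anyDuplicated(v4$kmers), 0L)

  v5 <- build_vocabulary(c("S", "M", "H", "I", "T"), 3)
  expect_identical(v5$V, 125L)
  v6 <- build_vocabulary(c("S", "M", "H", "I", "T", "F"), 3)
  expect_identical(v6$V, 216L)

  v1 <- build_vocabulary(c("A", "C"), 1)
  expect_identical(v1$kmers, c("A", "C"))
})

test_that("tokenize slides an overlapping window of width k", {
  v <- build_vocabulary(c("A", "C", "G", "U"), 3)
  expect_identical(v$kmers[tokenize("AUUGC", v)], c("AUU", "UUG", "UGC"))
  v6 <- build_vocabulary(c("S", "M", "H", "I", "T", "F"), 3)
  expect_identical(v6$kmers[tokenize("FHSIH", v6)], c("FHS", "HSI", "SIH"))
  expect_error(tokenize("AU", v), class = "kmerbind_too_short")
  expect_error(tokenize("AUXGC", v), class = "kmerbind_alphabet_error")
  # token count conservation: L - k + 1
  set.seed(9)
  for (L in c(3, 10, 57)) {
    expect_length(tokenize(random_rna(L), v), L - 2L)
  }
})

test_that("skipgram_pairs enumerates in-bounds (center, context) pairs", {
  expect_identical(skipgram_pairs(c(10L, 20L, 30L), 1L),
                   cbind(center = c(10L, 20L, 20L, 30L),
                         context = c(20L, 10L, 30L, 20L)))
  expect_identical(nrow(skipgram_pairs(5L, 3L)), 0L)
  # window >= n gives all ordered pairs: n(n-1)
  for (n in c(2, 5, 9)) {
    toks <- seq_len(n)
    expect_identical(nrow(skipgram_pairs(toks, n)), as.integer(n * (n - 1)))
  }
})

test_that("analytic skip-gram gradient matches central differences", {
  set.seed(7)
  d <- 8
  u <- rnorm(d) * 0.3
  wp <- rnorm(d) * 0.3
  Wn <- matrix(rnorm(4 * d) * 0.3, 4, d)
  obj <- function(u, wp, Wn) kmerbind:::sg_pair_objective(u, wp, Wn)
  g <- kmerbind:::sg_pair_gradient(u, wp, Wn)
  h <- 1e-6
  num_du <- vapply(seq_len(d), function(i) {
    e <- numeric(d); e[i] <- h
    (obj(u + e, wp, Wn) - obj(u - e, wp, Wn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_du - g$du)) / max(abs(g$du)), 1e-5)
  num_dw <- vapply(seq_len(d), function(i) {
    e <- numeric(d); e[i] <- h
    (obj(u, wp + e, Wn) - obj(u, wp - e, Wn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_dw - g$dw_pos)) / max(abs(g$dw_pos)), 1e-5)
  num_dn <- vapply(seq_len(d), function(i) {
    e <- matrix(0, 4, d); e[2, i] <- h
    (obj(u, wp, Wn + e) - obj(u, wp, Wn - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num_dn - g$dW_neg[2, ])), 1e-6)
})

test_that("training with epochs = 0 returns the seeded initialization", {
  v <- build_vocabulary(c("A", "C", "G", "U"), 2)
  corpus <- list(tokenize("ACGUACGU", v))
  cfg <- skipgram_config(dim = 5, epochs = 0, seed = 33)
  emb <- train_skipgram(corpus, v, cfg)
  expect_true(all(emb$output_vectors == 0))
  expect_true(all(abs(emb$input_vectors) < 0.5 / 5))
  emb2 <- train_skipgram(corpus, v, cfg)
  expect_identical(emb$input_vectors, emb2$input_vectors)
})

test_that("skip-gram objective improves with training on a fixed corpus", {
  v <- build_vocabulary(c("A", "C", "G", "U"), 1)
  set.seed(5)
  corpus <- lapply(1:20, function(i) tokenize(random_rna(30), v))
  pairs <- do.call(rbind, lapply(corpus, skipgram_pairs, m = 2L))
  noise <- kmerbind:::sg_noise_distribution(unlist(corpus), v$V, 0.75)
  objs <- vapply(c(0L, 1L, 3L, 8L), function(ep) {
    emb <- train_skipgram(corpus, v,
                          skipgram_config(window = 2, dim = 6, epochs = ep,
                                          lr = 0.01, seed = 11))
    skipgram_objective(emb, pairs, noise)
  }, numeric(1))
  # monotone trend with a small tolerance for stochastic wiggle
  expect_true(all(diff(objs) > -1e-3))
  expect_gt(objs[4], objs[1])
})

test_that("tokens sharing contexts end up closer than tokens that never do", {
  v <- build_vocabulary(c("A", "C", "G", "U"), 1)
  # A and C always appear between two G; U only ever with itself
  corpus <- c(rep(list(tokenize("GAGGAG", v), tokenize("GCGGCG", v)), 40),
              rep(list(tokenize("UUUUUU", v)), 40))
  emb <- train_skipgram(corpus, v, skipgram_config(window = 1, dim = 8,
                                                   epochs = 12, batch = 64,
                                                   seed = 2))
  U <- emb$input_vectors
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  iA <- match("A", v$kmers); iC <- match("C", v$kmers); iU <- match("U", v$kmers)
  expect_gt(cosine(U[iA, ], U[iC, ]), cosine(U[iA, ], U[iU, ]))
})

test_that("noise distribution follows unigram^power and sampled draws match it", {
  v <- build_vocabulary(c("A", "C"), 1)
  toks <- c(rep(1L, 90), rep(2L, 10))
  p <- kmerbind:::sg_noise_distribution(toks, 2L, 0.75)
  expect_equal(p, c(90^0.75, 10^0.75) / (90^0.75 + 10^0.75), tolerance = 1e-12)
  set.seed(4)
  draws <- sample.int(2L, 1e5, replace = TRUE, prob = p)
  gof <- chisq.test(tabulate(draws, 2L), p = p)
  expect_gt(gof$p.value, 1e-4)
})

test_that("embed_tokens looks up rows without mutating the embedding", {
  v <- build_vocabulary(c("A", "C", "G", "U"), 3)
  emb <- train_skipgram(list(tokenize("ACGUACGUAC", v)), v,
                        skipgram_config(dim = 10, epochs = 0, seed = 1))
  toks <- tokenize("AUUGC", v)
  m <- embed_tokens(toks, emb)
  expect_identical(dim(m), c(3L, 10L))
  expect_identical(m[1, ], emb$input_vectors[toks[1], ])
  # repeated token gives identical rows
  toks2 <- c(toks[1], toks[1])
  m2 <- embed_tokens(toks2, emb)
  expect_identical(m2[1, ], m2[2, ])
  expect_error(embed_tokens(65L, emb), class = "kmerbind_index_error")
})

test_that("word2vec text format round-trips", {
  v <- build_vocabulary(c("A", "C"), 2)
  emb <- train_skipgram(list(c(1L, 2L, 3L, 4L, 1L, 2L)), v,
                        skipgram_config(dim = 4, epochs = 1, seed = 6))
  p <- tempfile(fileext = ".txt")
  write_embedding_text(emb, p)
  back <- read_embedding_text(p)
  expect_identical(back$kmers, v$kmers)
  expect_equal(back$vectors, unname(emb$input_vectors), tolerance = 1e-12)
})
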
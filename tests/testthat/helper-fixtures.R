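# Shared fixtures: everything is generated in code at test time.

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

random_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                                collapse = "")

# Uniformly structured random dot-bracket string of length n: at each step
# open a pair, close an open pair, or emit a dot, keeping balance feasible.
random_dot_bracket <- function(n) {
  out <- character(n)
  open <- 0L
  for (i in seq_len(n)) {
    remaining <- n - i + 1L
    choices <- c(".")
    if (remaining > open + 1L) choices <- c(choices, "(")
    if (open > 0L) choices <- c(choices, ")")
    if (open == remaining) choices <- ")"
    ch <- sample(choices, 1L)
    out[i] <- ch
    if (ch == "(") open <- open + 1L
    if (ch == ")") open <- open - 1L
  }
  # close any leftovers by converting trailing dots; simplest: append closes
  if (open > 0L) out <- c(out[seq_len(n - open)], rep(")", open))
  s <- paste(out, collapse = "")
  # validity guaranteed by construction only if enough closers; re-check:
  tryCatch({ parse_dot_bracket(s); s }, error = function(e) strrep(".", n))
}

# Tiny labeled dataset with a strong implanted motif, for training mechanics.
tiny_motif_dataset <- function(n_per_class = 30L, L = 40L, motif = "UGCAUGU",
                               seed = 42L) {
  set.seed(seed)
  pos <- vapply(seq_len(n_per_class), function(i) {
    s <- random_rna(L)
    p <- sample.int(L - nchar(motif) + 1L, 1L)
    substr(s, p, p + nchar(motif) - 1L) <- motif
    s
  }, character(1L))
  neg <- vapply(seq_len(n_per_class), function(i) random_rna(L), character(1L))
  new_labeled_dataset(id = sprintf("ex%03d", seq_len(2L * n_per_class)),
                      sequence = c(pos, neg),
                      label = rep(c(1L, 0L), each = n_per_class),
                      provenance = "tiny fixture")
}

dinuc_counts <- function(s) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  table(paste0(x[-length(x)], x[-1L]))
}
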
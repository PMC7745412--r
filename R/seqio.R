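# Sequence input/output: FASTA reading and writing, residue normalization, and
# assembly of labeled positive/negative datasets in the GraphProt two-file
# convention (one FASTA of bound sites, one of unbound sites).

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases the input and converts T to U (DNA input is silently treated as
#' RNA, since CLIP-derived datasets mix both conventions). Any remaining
#' character outside `{A,C,G,U}` is an error in strict mode; in permissive mode
#' each such character is replaced by a base drawn uniformly from the four
#' unambiguous bases, reproducibly under `seed`.
#'
#' @param raw Character scalar, the raw residue string.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @param seed Integer seed used only in permissive mode.
#' @return A character scalar over `{A,C,G,U}`.
#' @examples
#' normalize_rna("acgt")            # "ACGU"
#' normalize_rna("ACGN", mode = "permissive", seed = 1)
#' @export
normalize_rna <- function(raw, mode = c("strict", "permissive"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    abort("kmerbind_invalid_input", "normalize_rna: 'raw' must be a non-empty string")
  s <- chartr("tT", "uU", raw)
  s <- toupper(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% RNA_ALPHABET)
  if (length(bad)) {
    if (mode == "strict")
      abort("kmerbind_invalid_residue",
            "invalid residue '%s' at position %d (strict mode)", ch[bad[1L]], bad[1L])
    ch[bad] <- with_seed(seed, sample(RNA_ALPHABET, length(bad), replace = TRUE))
  }
  paste(ch, collapse = "")
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-line sequence bodies are allowed. Residues are passed through
#' [normalize_rna()]; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param mode Normalization mode, see [normalize_rna()].
#' @param seed Seed for permissive-mode normalization.
#' @return A named character vector of residue strings; names are the FASTA
#'   identifiers (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, mode = "strict", seed = NULL) {
  if (!file.exists(path))
    abort("kmerbind_io_error", "FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort("kmerbind_parse_error",
                                            "malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0L)
    abort("kmerbind_empty_input", "FASTA file '%s' contains no records", path)
  w <- Biostrings::width(set)
  if (any(w == 0L))
    abort("kmerbind_parse_error", "FASTA record '%s' in '%s' has an empty sequence",
          names(set)[which(w == 0L)[1L]], path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  res <- vapply(as.character(set), normalize_rna, character(1L),
                mode = mode, seed = seed, USE.NAMES = FALSE)
  names(res) <- ids
  res
}

#' Write sequences to a FASTA file (one line per sequence)
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) abort("kmerbind_empty_input", "no sequences to write")
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", as.character(seqs)), path)
  invisible(path)
}

#' Assemble a labeled dataset from positive and negative FASTA files
#'
#' Positives are labeled 1 (binding), negatives 0. An optional shape file (one
#' six-letter shape string per line, blank lines ignored) supplies per-sequence
#' structural context, order-matched to the concatenation of positives then
#' negatives.
#'
#' @param pos_path FASTA of positive (bound) sequences.
#' @param neg_path FASTA of negative (unbound) sequences.
#' @param shape_path Optional path to a plain-text shape-string file.
#' @param mode Normalization mode passed to [read_fasta()].
#' @param seed Seed for permissive normalization.
#' @return A `labeled_dataset`: list with `id`, `sequence`, `shape` (character
#'   or `NA`), `label` (integer 0/1) vectors and a `provenance` attribute.
#' @export
load_labeled_dataset <- function(pos_path, neg_path, shape_path = NULL,
                                 mode = "strict", seed = NULL) {
  pos <- read_fasta(pos_path, mode = mode, seed = seed)
  neg <- read_fasta(neg_path, mode = mode, seed = seed)
  seqs <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  shapes <- rep(NA_character_, length(seqs))
  if (!is.null(shape_path)) {
    shapes <- load_structure_strings(shape_path, expected_lengths = nchar(seqs),
                                     ids = names(seqs))
  }
  new_labeled_dataset(id = names(seqs), sequence = unname(seqs),
                      shape = unname(shapes), label = labels,
                      provenance = paste(c(pos_path, neg_path, shape_path),
                                         collapse = " + "))
}

#' Construct a labeled dataset from vectors
#'
#' Low-level constructor used by [load_labeled_dataset()] and the synthetic
#' generator.
#'
#' @param id,sequence,shape,label Parallel vectors; `shape` may be `NA`.
#' @param provenance Free-text origin of the data.
#' @return A `labeled_dataset` object.
#' @export
new_labeled_dataset <- function(id, sequence, shape = NA_character_, label,
                                provenance = "in-memory") {
  n <- length(sequence)
  shape <- rep_len(shape, n)
  stopifnot(length(id) == n, length(label) == n)
  ok <- is.na(shape) | nchar(shape) == nchar(sequence)
  if (!all(ok))
    abort("kmerbind_alignment_error",
          "shape length != sequence length for record '%s'", id[which(!ok)[1L]])
  ds <- list(id = as.character(id), sequence = as.character(sequence),
             shape = as.character(shape), label = as.integer(label))
  attr(ds, "provenance") <- provenance
  class(ds) <- "labeled_dataset"
  ds
}

#' @export
length.labeled_dataset <- function(x) length(x$sequence)

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d examples (%d positive, %d negative), shapes: %s\n",
              length(x), sum(x$label == 1L), sum(x$label == 0L),
              if (all(is.na(x$shape))) "absent" else "present"))
  cat("provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

# Subset a labeled dataset by index, keeping provenance.
#' @export
`[.labeled_dataset` <- function(x, i) {
  new_labeled_dataset(x$id[i], x$sequence[i], x$shape[i], x$label[i],
                      provenance = attr(x, "provenance"))
}
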
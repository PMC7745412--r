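# Secondary-structure handling: dot-bracket parsing and per-position loop-type
# annotation into the six-letter shape alphabet used alongside the nucleotide
# sequence — S (stem), M (multiloop), H (hairpin loop), I (internal loop),
# T (dangling end), F (dangling start).
#
# The per-position classification applied here: paired positions are S; an
# unpaired position enclosed by a pair is classified by the number of branch
# helices directly inside its innermost enclosing pair (0 -> H, 1 -> I,
# >=2 -> M); an unpaired position outside all pairs is F before the first
# paired position and T otherwise (including gaps between top-level helices,
# treated as external/dangling-end). A fully unpaired structure is all T.

SHAPE_ALPHABET <- c("S", "M", "H", "I", "T", "F")

#' Parse a dot-bracket string into a base-pair table
#'
#' Matched parentheses are paired by stack discipline; dots are unpaired.
#' Pseudoknots cannot be expressed in plain dot-bracket and are thus excluded.
#'
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return An integer vector `partner` of the same length: `partner[i]` is the
#'   1-based partner of position i, or 0 if unpaired.
#' @examples
#' parse_dot_bracket("((...))")  # c(7, 6, 0, 0, 0, 2, 1)
#' @export
parse_dot_bracket <- function(db) {
  if (!is.character(db) || length(db) != 1L || nchar(db) == 0L)
    abort("kmerbind_invalid_input", "parse_dot_bracket: need a non-empty string")
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad))
    abort("kmerbind_structure_parse_error",
          "illegal dot-bracket character '%s' at position %d", ch[bad[1L]], bad[1L])
  n <- length(ch)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        abort("kmerbind_structure_parse_error",
              "unbalanced ')' at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack))
    abort("kmerbind_structure_parse_error",
          "unmatched '(' at position %d", stack[length(stack)])
  partner
}

#' Annotate loop types of a secondary structure
#'
#' Maps a base-pair table to the six-letter shape string described above.
#'
#' @param partner Integer pair table from [parse_dot_bracket()].
#' @return A shape string of the same length over `{S,M,H,I,T,F}`.
#' @examples
#' annotate_shapes(parse_dot_bracket("..((((...)))).."))  # "FFSSSSHHHSSSSTT"
#' @export
annotate_shapes <- function(partner) {
  n <- length(partner)
  if (n == 0L) abort("kmerbind_invalid_input", "empty pair table")
  if (any(partner < 0L | partner > n) || any(partner == seq_len(n)))
    abort("kmerbind_invalid_input", "pair table positions out of range")
  ip <- which(partner > 0L)
  if (any(partner[partner[ip]] != ip))
    abort("kmerbind_invalid_input", "pair table is not a valid involution")
  out <- character(n)
  paired <- partner != 0L
  out[paired] <- "S"
  # enclosing[i]: opening position of the innermost pair strictly containing i
  enclosing <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (paired[i] && partner[i] > i) {          # opening
      enclosing[i] <- if (length(stack)) stack[length(stack)] else 0L
      stack <- c(stack, i)
    } else if (paired[i]) {                     # closing
      stack <- stack[-length(stack)]
      enclosing[i] <- if (length(stack)) stack[length(stack)] else 0L
    } else {
      enclosing[i] <- if (length(stack)) stack[length(stack)] else 0L
    }
  }
  # branches[o]: number of helices directly inside the pair opening at o
  branches <- integer(n)
  for (i in seq_len(n)) {
    if (paired[i] && partner[i] > i && enclosing[i] > 0L)
      branches[enclosing[i]] <- branches[enclosing[i]] + 1L
  }
  if (!any(paired)) return(strrep("T", n))  # fully unpaired: dangling end
  un <- which(!paired)
  if (length(un)) {
    first_p <- min(which(paired))
    for (i in un) {
      o <- enclosing[i]
      if (o == 0L) {
        out[i] <- if (i < first_p) "F" else "T"
      } else {
        b <- branches[o]
        out[i] <- if (b == 0L) "H" else if (b == 1L) "I" else "M"
      }
    }
  }
  paste(out, collapse = "")
}

#' Load precomputed shape strings from a plain-text file
#'
#' One shape string per line, blank lines ignored, order-matched to the
#' sequences they annotate. Each line is validated against the six-letter
#' alphabet and, when `expected_lengths` is given, against its sequence length.
#'
#' @param path Path to the shape file.
#' @param expected_lengths Optional integer vector of sequence lengths.
#' @param ids Optional record identifiers used in error messages.
#' @return Character vector of validated shape strings.
#' @export
load_structure_strings <- function(path, expected_lengths = NULL, ids = NULL) {
  if (!file.exists(path))
    abort("kmerbind_io_error", "shape file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!is.null(expected_lengths) && length(lines) != length(expected_lengths))
    abort("kmerbind_alignment_error",
          "shape file '%s' has %d entries for %d sequences",
          path, length(lines), length(expected_lengths))
  for (i in seq_along(lines)) {
    ch <- strsplit(lines[i], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% SHAPE_ALPHABET)
    if (length(bad))
      abort("kmerbind_alphabet_error",
            "illegal shape character '%s' at line %d, position %d",
            ch[bad[1L]], i, bad[1L])
    if (!is.null(expected_lengths) && length(ch) != expected_lengths[i]) {
      who <- if (!is.null(ids)) ids[i] else as.character(i)
      abort("kmerbind_alignment_error",
            "shape length %d != sequence length %d for record '%s'",
            length(ch), expected_lengths[i], who)
    }
  }
  lines
}

#' Annotate shapes for a file of dot-bracket structures
#'
#' Accepts Vienna-style plain text (one structure per line) or FASTA-like
#' triplets (header / sequence / structure); lines containing only dot-bracket
#' characters are taken as structures.
#'
#' @param path Input path.
#' @return Character vector of shape strings, one per structure line.
#' @export
annotate_dot_bracket_file <- function(path) {
  if (!file.exists(path)) abort("kmerbind_io_error", "file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  db <- lines[nzchar(lines) & grepl("^[().]+$", lines)]
  if (length(db) == 0L)
    abort("kmerbind_empty_input", "no dot-bracket lines found in '%s'", path)
  vapply(db, function(s) annotate_shapes(parse_dot_bracket(s)), character(1L),
         USE.NAMES = FALSE)
}
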
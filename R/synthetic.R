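# Synthetic benchmark generator: positives carry an implanted consensus motif
# on random background (optionally inside a hairpin-loop structural context);
# negatives are dinucleotide-shuffled positives (composition-matched), pure
# background, or motif-bearing sequences whose structural context is broken.
# Ground truth (implant window, context flag) is recorded for every positive,
# so representation and architecture claims can be tested with known signal.

#' Specification of a synthetic dataset
#'
#' @param n_pos,n_neg Example counts per class.
#' @param length_range Two integers, min and max sequence length (nt); lengths
#'   are drawn uniformly.
#' @param background_composition Probabilities over A, C, G, U (sum to 1).
#' @param motif Consensus motif over `{A,C,G,U}`; must be shorter than the
#'   minimum length (with room for the structural context stems).
#' @param per_position_mutation_rate Probability that each implanted motif
#'   position is mutated to a random different base (controls motif strength).
#' @param structural_context `"none"`, `"hairpin_loop"` (motif inside the
#'   hairpin loop of a stem-loop) or `"stem"`.
#' @param coupling Probability a positive carries its motif inside the stated
#'   context; otherwise the context is placed independently of the motif.
#' @param negative_mode `"shuffle"` (dinucleotide-shuffled positives),
#'   `"background"` (pure background), `"motif_out_of_context"` (negatives
#'   also carry the motif, but never inside the structural context — structure
#'   is then the only reliable signal), or `"decoy_pair"` (with `motif2`:
#'   negatives carry both motifs at independent random positions, so only the
#'   spacing between them separates the classes).
#' @param motif2 Optional second motif implanted downstream of the first.
#' @param gap_range Two integers: gap (nt) between the motifs when `motif2`
#'   is given.
#' @param stem_length Stem length (nt) of the generated hairpin context.
#' @param seed RNG seed; generation is bitwise-reproducible from the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 500L, n_neg = 500L,
                           length_range = c(150L, 375L),
                           background_composition = c(A = 0.25, C = 0.25,
                                                      G = 0.25, U = 0.25),
                           motif = "UGCAUGU",
                           per_position_mutation_rate = 0.05,
                           structural_context = c("none", "hairpin_loop", "stem"),
                           coupling = 1,
                           negative_mode = c("shuffle", "background",
                                             "motif_out_of_context",
                                             "decoy_pair"),
                           motif2 = NULL, gap_range = c(10L, 30L),
                           stem_length = 6L, seed = 1L) {
  structural_context <- match.arg(structural_context)
  negative_mode <- match.arg(negative_mode)
  if (abs(sum(background_composition) - 1) > 1e-9)
    abort("kmerbind_spec_error", "background composition must sum to 1")
  if (any(background_composition < 0))
    abort("kmerbind_spec_error", "negative composition probability")
  if (per_position_mutation_rate < 0 || per_position_mutation_rate > 1 ||
      coupling < 0 || coupling > 1)
    abort("kmerbind_spec_error", "rates must lie in [0, 1]")
  if (!grepl("^[ACGU]+$", motif))
    abort("kmerbind_spec_error", "motif must be over {A,C,G,U}")
  if (negative_mode == "decoy_pair" && is.null(motif2))
    abort("kmerbind_spec_error", "decoy_pair negatives need motif2")
  room <- nchar(motif) + if (!is.null(motif2)) nchar(motif2) + max(gap_range) else 0L
  room <- room + if (structural_context != "none") 2L * stem_length + 2L else 0L
  if (room >= min(length_range))
    abort("kmerbind_spec_error",
          "motif/context (%d nt) does not fit the minimum length %d",
          room, min(length_range))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 background_composition = background_composition,
                 motif = motif,
                 per_position_mutation_rate = per_position_mutation_rate,
                 structural_context = structural_context, coupling = coupling,
                 negative_mode = negative_mode, motif2 = motif2,
                 gap_range = as.integer(gap_range),
                 stem_length = as.integer(stem_length), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a background sequence
#'
#' I.i.d. draws from the base composition.
#'
#' @param length Sequence length.
#' @param composition Probabilities over A, C, G, U.
#' @param seed Optional seed (omit when called inside a seeded generator).
#' @return Residue string.
#' @export
sample_background <- function(length, composition = c(0.25, 0.25, 0.25, 0.25),
                              seed = NULL) {
  if (length < 1L) abort("kmerbind_spec_error", "length must be >= 1")
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0))
    abort("kmerbind_spec_error", "invalid composition")
  with_seed(seed,
            paste(sample(RNA_ALPHABET, length, replace = TRUE, prob = composition),
                  collapse = ""))
}

#' Implant a (possibly mutated) motif into a sequence
#'
#' The motif is copied over a window; each position is independently mutated
#' to a uniformly chosen *different* base with the given probability.
#'
#' @param seq Host sequence.
#' @param motif Consensus motif.
#' @param mutation_rate Per-position mutation probability.
#' @param position 1-based start, or `NULL` for a uniform random admissible
#'   start.
#' @param seed Optional seed.
#' @return List with `sequence` and `position` (0-based, half-open window
#'   `[position, position + nchar(motif))`).
#' @export
implant_motif <- function(seq, motif, mutation_rate = 0, position = NULL,
                          seed = NULL) {
  L <- nchar(seq); w <- nchar(motif)
  if (w > L) abort("kmerbind_spec_error", "motif longer than sequence")
  with_seed(seed, {
    pos <- as.integer(position %||% sample.int(L - w + 1L, 1L))
    if (pos < 1L || pos + w - 1L > L)
      abort("kmerbind_spec_error", "implant window outside sequence")
    mch <- strsplit(motif, "", fixed = TRUE)[[1L]]
    mut <- runif(w) < mutation_rate
    if (any(mut)) {
      mch[mut] <- vapply(mch[mut], function(b)
        sample(setdiff(RNA_ALPHABET, b), 1L), character(1L))
    }
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    ch[pos:(pos + w - 1L)] <- mch
    list(sequence = paste(ch, collapse = ""), position = pos - 1L)
  })
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erikson shuffle: a random Eulerian walk over the dinucleotide
#' transition multigraph, so the returned sequence has exactly the input's
#' dinucleotide (and hence mononucleotide) counts, starts with the same first
#' base and ends with the same last base.
#'
#' @param seq Residue string (length >= 2).
#' @param seed Optional seed.
#' @return Shuffled residue string.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) abort("kmerbind_spec_error", "need length >= 2 to shuffle")
  with_seed(seed, {
    verts <- unique(ch)
    from <- ch[-n]; to <- ch[-1L]
    sink <- ch[n]
    # adjacency: outgoing target list per vertex
    adj <- split(to, factor(from, levels = verts))
    repeat {
      # choose a random "last edge" per non-sink vertex; accept if those edges
      # form a tree pointing to the sink (Altschul-Erikson condition)
      last <- vapply(verts, function(v) {
        if (v == sink || length(adj[[v]]) == 0L) NA_character_
        else sample(adj[[v]], 1L)
      }, character(1L))
      ok <- TRUE
      for (v in verts) {
        if (v == sink || is.na(last[v])) next
        seen <- character(0); cur <- v
        while (cur != sink) {
          if (cur %in% seen || is.na(last[cur])) { ok <- FALSE; break }
          seen <- c(seen, cur); cur <- last[cur]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute remaining edges per vertex, append the reserved last edge
    lists <- lapply(verts, function(v) {
      out <- adj[[v]]
      if (v != sink && !is.na(last[v])) {
        i <- match(last[v], out)
        out <- out[-i]
      }
      out <- if (length(out)) sample(out) else character(0)
      if (v != sink && !is.na(last[v])) out <- c(out, last[v])
      out
    })
    names(lists) <- verts
    ptr <- setNames(rep(1L, length(verts)), verts)
    res <- character(n); res[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    paste(res, collapse = "")
  })
}

# Hairpin dot-bracket covering [loop_start, loop_end] (1-based, inclusive)
# with stems of the given length immediately flanking the loop.
#' @keywords internal
#' @noRd
hairpin_dot_bracket <- function(L, loop_start, loop_end, stem) {
  stopifnot(loop_start - stem >= 1L, loop_end + stem <= L)
  paste0(strrep(".", loop_start - stem - 1L), strrep("(", stem),
         strrep(".", loop_end - loop_start + 1L), strrep(")", stem),
         strrep(".", L - loop_end - stem))
}

#' Generate a labeled synthetic dataset with ground truth
#'
#' Positives are background sequences with the motif implanted; with
#' `structural_context = "hairpin_loop"` each positive carries a shape string
#' from a constructed stem-loop whose hairpin loop covers the implant window
#' with probability `coupling` (otherwise the hairpin is placed independently
#' of the motif). Negatives follow `negative_mode`; their shape strings are
#' context-free (a hairpin at a random position). Shape strings are produced
#' by annotating the constructed dot-bracket with [annotate_shapes()], so they
#' always validate against the structure module.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a `labeled_dataset`) and `truth`, a data frame
#'   (`id`, `label`, `implant_start`, `implant_end`, 0-based half-open, `NA`
#'   for motif-free examples, and `in_context`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lmin <- spec$length_range[1L]; lmax <- spec$length_range[2L]
    stem <- spec$stem_length
    wants_context <- spec$structural_context != "none"
    w1 <- nchar(spec$motif)

    make_one <- function(with_motif, in_context_allowed, avoid_overlap = FALSE) {
      L <- sample(lmin:lmax, 1L)
      s <- sample_background(L, spec$background_composition)
      implant <- c(NA_integer_, NA_integer_)
      in_ctx <- FALSE
      shape <- NA_character_
      margin <- stem + 1L                     # room for stems + 1 nt dangle
      if (with_motif) {
        if (!is.null(spec$motif2)) {
          # gap-constrained pair: sample the gap first so the pair always fits
          gap <- sample(spec$gap_range[1L]:spec$gap_range[2L], 1L)
          span <- w1 + gap + nchar(spec$motif2)
          pos <- sample((margin + 1L):(L - span + 1L - margin), 1L)
          imp <- implant_motif(s, spec$motif, spec$per_position_mutation_rate,
                               position = pos)
          s <- implant_motif(imp$sequence, spec$motif2,
                             spec$per_position_mutation_rate,
                             position = pos + w1 + gap)$sequence
          implant <- c(imp$position, imp$position + w1)
        } else {
          pos <- sample((margin + 1L):(L - w1 + 1L - margin), 1L)
          imp <- implant_motif(s, spec$motif, spec$per_position_mutation_rate,
                               position = pos)
          s <- imp$sequence
          implant <- c(imp$position, imp$position + w1)
        }
        in_ctx <- in_context_allowed && wants_context &&
          runif(1L) < spec$coupling
      }
      if (wants_context) {
        if (in_ctx && spec$structural_context == "hairpin_loop") {
          db <- hairpin_dot_bracket(L, implant[1L] + 1L, implant[2L], stem)
        } else if (in_ctx && spec$structural_context == "stem") {
          # motif inside one strand of a stem: pair the window with a distal run
          a1 <- implant[1L] + 1L; a2 <- implant[2L]
          b2 <- L - 1L; b1 <- b2 - w1 + 1L
          db <- if (b1 > a2 + 3L)
            paste0(strrep(".", a1 - 1L), strrep("(", w1),
                   strrep(".", b1 - a2 - 1L), strrep(")", w1),
                   strrep(".", L - b2))
          else hairpin_dot_bracket(L, a1, a2, stem)
        } else {
          # context placed independently of any motif; for out-of-context
          # decoys the loop must not cover the motif window, otherwise a
          # fraction of decoys would accidentally present the motif in
          # context and blur the class boundary
          loop_len <- max(w1, 6L)
          repeat {
            ls <- sample((stem + 2L):(L - loop_len - stem), 1L)
            if (!avoid_overlap || is.na(implant[1L]) ||
                ls + loop_len - 1L < implant[1L] + 1L || ls > implant[2L])
              break
          }
          db <- hairpin_dot_bracket(L, ls, ls + loop_len - 1L, stem)
        }
        shape <- annotate_shapes(parse_dot_bracket(db))
      }
      list(seq = s, shape = shape, implant = implant, in_ctx = in_ctx)
    }

    pos_ex <- lapply(seq_len(spec$n_pos), function(i) make_one(TRUE, TRUE))

    neg_ex <- lapply(seq_len(spec$n_neg), function(i) {
      switch(spec$negative_mode,
        shuffle = {
          src <- pos_ex[[((i - 1L) %% spec$n_pos) + 1L]]
          list(seq = dinucleotide_shuffle(src$seq),
               shape = if (wants_context) {
                 # shape must match this sequence's length: regenerate on it
                 L <- nchar(src$seq)
                 loop_len <- max(w1, 6L)
                 ls <- sample((stem + 2L):(L - loop_len - stem), 1L)
                 annotate_shapes(parse_dot_bracket(
                   hairpin_dot_bracket(L, ls, ls + loop_len - 1L, stem)))
               } else NA_character_,
               implant = c(NA_integer_, NA_integer_), in_ctx = FALSE)
        },
        background = make_one(FALSE, FALSE),
        motif_out_of_context = make_one(TRUE, FALSE, avoid_overlap = TRUE),
        decoy_pair = {
          # both motifs present, positions independent: only spacing separates
          # decoys from the gap-constrained positives
          ex <- make_one(FALSE, FALSE)
          L <- nchar(ex$seq)
          margin <- stem + 1L
          w2 <- nchar(spec$motif2)
          p1 <- sample((margin + 1L):(L - w1 + 1L - margin), 1L)
          s2 <- implant_motif(ex$seq, spec$motif, spec$per_position_mutation_rate,
                              position = p1)$sequence
          repeat {
            p2 <- sample((margin + 1L):(L - w2 + 1L - margin), 1L)
            gap <- p2 - (p1 + w1)
            ok_sep <- p2 + w2 <= p1 || p2 >= p1 + w1   # non-overlapping
            if (ok_sep && (gap < spec$gap_range[1L] || gap > spec$gap_range[2L]))
              break
          }
          s2 <- implant_motif(s2, spec$motif2, spec$per_position_mutation_rate,
                              position = p2)$sequence
          list(seq = s2, shape = ex$shape,
               implant = c(NA_integer_, NA_integer_), in_ctx = FALSE)
        })
    })

    all_ex <- c(pos_ex, neg_ex)
    ids <- c(sprintf("pos_%04d", seq_len(spec$n_pos)),
             sprintf("neg_%04d", seq_len(spec$n_neg)))
    ds <- new_labeled_dataset(
      id = ids,
      sequence = vapply(all_ex, `[[`, character(1L), "seq"),
      shape = vapply(all_ex, `[[`, character(1L), "shape"),
      label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
      provenance = sprintf("synthetic(motif=%s, context=%s, neg=%s, seed=%d)",
                           spec$motif, spec$structural_context,
                           spec$negative_mode, spec$seed))
    truth <- data.frame(
      id = ids,
      label = ds$label,
      implant_start = vapply(all_ex, function(e) e$implant[1L], integer(1L)),
      implant_end = vapply(all_ex, function(e) e$implant[2L], integer(1L)),
      in_context = vapply(all_ex, `[[`, logical(1L), "in_ctx"),
      stringsAsFactors = FALSE)
    list(dataset = ds, truth = truth)
  })
}

#' Write a generated dataset to disk in the GraphProt file convention
#'
#' Writes `positives.fa`, `negatives.fa`, optional `shapes_pos.txt` /
#' `shapes_neg.txt` (one shape string per line) and `truth.tsv`.
#'
#' @param gen A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen$dataset
  pos <- ds$label == 1L
  write_fasta(setNames(ds$sequence[pos], ds$id[pos]), file.path(dir, "positives.fa"))
  write_fasta(setNames(ds$sequence[!pos], ds$id[!pos]), file.path(dir, "negatives.fa"))
  if (!all(is.na(ds$shape))) {
    writeLines(ds$shape[pos], file.path(dir, "shapes_pos.txt"))
    writeLines(ds$shape[!pos], file.path(dir, "shapes_neg.txt"))
  }
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
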
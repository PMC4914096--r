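# Assigning one sequence per staple group and deriving the complementary
# custom scaffold sequence; restriction-motif screening; cloning adapters.

#' Random DNA sequence with optional GC bounds
#'
#' Bases are i.i.d. uniform over A/C/G/T from R's global RNG stream. When GC
#' bounds are set in the config, sequences are re-drawn until the GC fraction
#' falls inside them (bounded retries).
#'
#' @param length Sequence length in nt (>= 1).
#' @param config Optional `design_config` supplying `gc_min`/`gc_max`.
#' @param retries Retry budget for the GC filter.
#' @return A base string.
#' @export
random_sequence <- function(length, config = NULL, retries = 1000L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1) {
    abort_restaple("sequence length must be >= 1", "restaple_argument_error")
  }
  gc_min <- if (is.null(config)) NULL else config$gc_min
  gc_max <- if (is.null(config)) NULL else config$gc_max
  for (i in seq_len(retries)) {
    s <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    if (is.null(gc_min) && is.null(gc_max)) return(s)
    gc <- gc_fraction(s)
    if (gc >= gc_min && gc <= gc_max) return(s)
  }
  abort_restaple(
    sprintf("no %d-nt sequence with GC in [%.2f, %.2f] after %d draws",
            length, gc_min, gc_max, retries),
    "restaple_generation_error"
  )
}

#' GC fraction of a base string
#' @param seq Base string.
#' @return Fraction of G + C bases.
#' @export
gc_fraction <- function(seq) {
  b <- split_bases(toupper(seq))
  sum(b %in% c("G", "C")) / length(b)
}

#' Assign one sequence to each staple group
#'
#' In predefined mode (`config$sequences` set) the given sequences are used
#' verbatim, matched to groups by length; any count or length mismatch is an
#' error listing the offending entries. In random mode one [random_sequence()]
#' per group is drawn; accidental duplicates are re-drawn so a candidate
#' always carries exactly `k_unique` distinct sequences.
#'
#' @param layout A `staple_layout`.
#' @param config A `design_config`.
#' @return A `sequence_set`: `sequences` (character, one per group),
#'   `provenance` ("random" or "predefined").
#' @export
assign_sequences <- function(layout, config) {
  stopifnot(inherits(layout, "staple_layout"), inherits(config, "design_config"))
  lens <- vapply(layout$staples, `[[`, integer(1), "length")
  group_len <- vapply(seq_len(layout$k), function(g) {
    gl <- unique(lens[layout$group_of == g])
    if (length(gl) != 1) {
      abort_restaple(sprintf("group %d is not length-homogeneous", g),
                     "restaple_assignment_error")
    }
    gl
  }, integer(1))

  if (!is.null(config$sequences)) {
    seqs <- config$sequences
    if (length(seqs) != layout$k) {
      abort_restaple(
        sprintf("predefined mode needs exactly %d sequences, got %d",
                layout$k, length(seqs)),
        "restaple_assignment_error"
      )
    }
    avail <- nchar(seqs)
    chosen <- integer(layout$k)
    used <- rep(FALSE, length(seqs))
    for (g in seq_len(layout$k)) {
      hit <- which(!used & avail == group_len[g])
      if (length(hit) == 0) {
        abort_restaple(
          sprintf("no unused predefined sequence of length %d for group %d (have lengths %s)",
                  group_len[g], g, paste(sort(avail[!used]), collapse = ", ")),
          "restaple_assignment_error"
        )
      }
      chosen[g] <- hit[1]
      used[hit[1]] <- TRUE
    }
    out <- seqs[chosen]
    provenance <- "predefined"
  } else {
    out <- character(layout$k)
    for (g in seq_len(layout$k)) {
      repeat {
        s <- random_sequence(group_len[g], config)
        if (!s %in% out) break
      }
      out[g] <- s
    }
    provenance <- "random"
  }
  structure(list(sequences = out, provenance = provenance), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence set: %d %s sequences, lengths %s nt\n",
              length(x$sequences), x$provenance,
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

#' Derive the forced-complementary scaffold sequence
#'
#' Walks the scaffold path 5' to 3'; at every position the staple base
#' hybridised at the same (helix, idx) cell dictates the scaffold base as its
#' Watson-Crick complement (staples run antiparallel, so a staple read 3'->5'
#' pairs with the scaffold read 5'->3'). Scaffold positions with no staple
#' coverage are filled from the seeded RNG stream and recorded.
#'
#' @param scaffold_path `strand_path` of kind "scaffold".
#' @param layout A `staple_layout` tiling (a subset of) the scaffold cells.
#' @param seqs A `sequence_set` for the layout's groups.
#' @return A `scaffold_sequence`: `bases`, `length`, `unpaired_positions`
#'   (1-based offsets along the scaffold path).
#' @export
derive_scaffold <- function(scaffold_path, layout, seqs) {
  stopifnot(inherits(scaffold_path, "strand_path"),
            inherits(layout, "staple_layout"),
            inherits(seqs, "sequence_set"))
  # staple-occupied cells with their base characters, 5'->3' per staple
  cell_key <- function(pos) pos[, 1] * 2^24 + pos[, 2]
  stap_keys <- vector("list", length(layout$staples))
  stap_base <- vector("list", length(layout$staples))
  for (i in seq_along(layout$staples)) {
    st <- layout$staples[[i]]
    sq <- seqs$sequences[layout$group_of[i]]
    if (nchar(sq) != st$length) {
      abort_restaple(sprintf("sequence for group %d does not match staple length",
                             layout$group_of[i]),
                     "restaple_assignment_error")
    }
    stap_keys[[i]] <- cell_key(st$path$positions)
    stap_base[[i]] <- split_bases(sq)
  }
  keys <- unlist(stap_keys, use.names = FALSE)
  if (anyDuplicated(keys)) {
    abort_restaple("two staples claim one cell", "restaple_overlap_error")
  }
  bases <- unlist(stap_base, use.names = FALSE)

  sk <- cell_key(scaffold_path$positions)
  hit <- match(sk, keys)
  out <- character(length(sk))
  paired <- !is.na(hit)
  out[paired] <- complement_bases(bases[hit[paired]])
  unpaired <- which(!paired)
  if (length(unpaired)) {
    out[unpaired] <- sample(DNA_BASES, length(unpaired), replace = TRUE)
  }
  structure(list(
    bases = paste(out, collapse = ""),
    length = length(out),
    unpaired_positions = unpaired
  ), class = "scaffold_sequence")
}

#' @export
print.scaffold_sequence <- function(x, ...) {
  cat(sprintf("scaffold sequence: %d nt, %d unpaired position(s)\n",
              x$length, length(x$unpaired_positions)))
  invisible(x)
}

#' Count overlapping motif occurrences on one strand
#'
#' Counts exact, possibly overlapping occurrences of `motif` in `seq` on the
#' given strand; call again with the motif's reverse complement to cover the
#' other strand of a duplex region.
#'
#' @param seq Base string (may be empty).
#' @param motif Non-empty base string.
#' @return Integer count.
#' @export
count_motif <- function(seq, motif) {
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) < 1) {
    abort_restaple("motif must be a non-empty base string", "restaple_argument_error")
  }
  if (nchar(seq) == 0) return(0L)
  Biostrings::countPattern(toupper(motif), Biostrings::DNAString(toupper(seq)))
}

#' Flank a scaffold with cloning adapters
#'
#' Returns `left + scaffold + right` (e.g. hairpin adapters encoding BtsCI
#' recognition sites for release of the scaffold from its phagemid vector).
#' The scaffold body is screened against the forbidden-motif list and a
#' warning reports the number of hits; screening is advisory and never fails.
#'
#' @param scaffold A `scaffold_sequence` or base string.
#' @param left,right Adapter base strings (may be empty).
#' @param forbidden_motifs Motifs to screen in the scaffold body.
#' @return The flanked base string, with attribute `forbidden_hits`.
#' @export
flank_with_adapters <- function(scaffold, left = "", right = "",
                                forbidden_motifs = c("GGATG", "CATCC")) {
  body <- if (inherits(scaffold, "scaffold_sequence")) scaffold$bases else scaffold
  for (a in list(left = left, right = right)) {
    if (nchar(a) > 0) check_acgt(toupper(a), "adapter")
  }
  hits <- sum(vapply(forbidden_motifs, function(m) count_motif(body, m), integer(1)))
  if (hits > 0) {
    warning(sprintf("scaffold body contains %d forbidden-motif hit(s)", hits),
            call. = FALSE)
  }
  out <- paste0(toupper(left), body, toupper(right))
  attr(out, "forbidden_hits") <- hits
  out
}
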
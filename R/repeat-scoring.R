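# Scaffold repetitiveness: the fraction of nucleotides covered by any
# w-base window that occurs more than once in the sequence.

#' Repeat coverage of a sequence
#'
#' Slides a `window`-nt window along the sequence; every window whose exact
#' forward-strand string occurs two or more times marks all of its positions,
#' at every occurrence, as covered. The repetitiveness score is the covered
#' fraction of the sequence. Sequences shorter than the window score 0. Input
#' is case-folded to upper case; non-ACGT characters are an error naming the
#' offending offset. The sequence is treated as linear (no wraparound
#' windows), matching a restriction-released linear scaffold.
#'
#' Window matching is hash-based (O(L w)); the test suite pins its output to
#' a brute-force all-pairs comparison oracle.
#'
#' @param seq Base string.
#' @param window Window length in nt (>= 2); 12 by default, the minimum
#'   repeat length used for scaffold screening.
#' @param include_revcomp Also count a window as repeated when its reverse
#'   complement occurs elsewhere in the sequence (off by default: scaffold
#'   repetitiveness is a same-strand notion; the flag exists for
#'   exploration).
#' @return A `repeat_report`: `window`, `sequence_length`,
#'   `duplicated_window_count` (window start positions whose window occurs
#'   more than once), `covered_mask` (per-position logical) and
#'   `coverage_fraction`.
#' @export
repeat_coverage <- function(seq, window = 12L, include_revcomp = FALSE) {
  window <- as.integer(window)
  if (is.na(window) || window < 2) {
    abort_restaple("window must be >= 2", "restaple_argument_error")
  }
  seq <- toupper(seq)
  check_acgt(seq, "sequence")
  L <- nchar(seq)
  if (L < window) {
    return(new_repeat_report(window, L, 0L, rep(FALSE, L)))
  }
  n_win <- L - window + 1L
  w <- substring(seq, seq_len(n_win), seq_len(n_win) + window - 1L)
  if (include_revcomp) {
    # occurrences of each window on either strand; a window pairing only with
    # its own offset (self reverse-complementary) does not count as a repeat
    rcw <- revcomp_windows(seq, window)
    uw <- unique(w)
    wi <- match(w, uw)
    fwd <- tabulate(wi, nbins = length(uw))
    mi <- match(rcw, uw)
    rcc <- tabulate(mi[!is.na(mi)], nbins = length(uw))
    dup <- (fwd[wi] + rcc[wi] - (w == rcw)) >= 2
  } else {
    dup <- duplicated(w) | duplicated(w, fromLast = TRUE)
  }
  starts <- which(dup)
  mask <- cover_mask(starts, window, L)
  new_repeat_report(window, L, length(starts), mask)
}

#' @keywords internal
#' @noRd
revcomp_windows <- function(seq, window) {
  rcs <- revcomp(seq)
  L <- nchar(seq)
  n_win <- L - window + 1L
  # window i (1-based) of seq reverse-complements to window (n_win - i + 1) of rc(seq)
  rev(substring(rcs, seq_len(n_win), seq_len(n_win) + window - 1L))
}

#' @keywords internal
#' @noRd
cover_mask <- function(starts, window, L) {
  if (length(starts) == 0) return(rep(FALSE, L))
  d <- integer(L + 1L)
  for (s in starts) {
    d[s] <- d[s] + 1L
    d[s + window] <- d[s + window] - 1L
  }
  cumsum(d[seq_len(L)]) > 0
}

#' @keywords internal
#' @noRd
new_repeat_report <- function(window, L, dup_count, mask) {
  structure(list(
    window = window,
    sequence_length = L,
    duplicated_window_count = dup_count,
    covered_mask = mask,
    coverage_fraction = if (L == 0) 0 else sum(mask) / L
  ), class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf(
    "repeat coverage (window %d nt): %.1f%% of %d nt in repetitive motifs (%d duplicated window positions)\n",
    x$window, 100 * x$coverage_fraction, x$sequence_length, x$duplicated_window_count
  ))
  invisible(x)
}

#' Covered intervals of a repeat report
#'
#' @param report A `repeat_report`.
#' @return Data frame of 0-based, half-open `[start, end)` covered intervals.
#' @export
covered_intervals <- function(report) {
  stopifnot(inherits(report, "repeat_report"))
  r <- rle(report$covered_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Score every record of a FASTA file
#'
#' Scoring-only mode: reads a FASTA file (e.g. the M13mp18 scaffold for the
#' standard-origami baseline) and reports per-record repeat coverage.
#' Optionally writes the covered intervals of each record to a BED-like file
#' (0-based, half-open; columns: record, start, end).
#'
#' @param file FASTA path.
#' @param window Window length in nt.
#' @param bed Optional path for the covered-intervals BED file.
#' @return Data frame: `record`, `length`, `duplicated_window_count`,
#'   `coverage_fraction`.
#' @export
score_fasta <- function(file, window = 12L, bed = NULL) {
  xs <- Biostrings::readDNAStringSet(file)
  if (length(xs) == 0) {
    abort_restaple("FASTA file holds no records", "restaple_io_error")
  }
  reports <- lapply(as.character(xs), repeat_coverage, window = window)
  out <- data.frame(
    record = names(xs),
    length = vapply(reports, `[[`, integer(1), "sequence_length"),
    duplicated_window_count = vapply(reports, `[[`, integer(1), "duplicated_window_count"),
    coverage_fraction = vapply(reports, `[[`, numeric(1), "coverage_fraction"),
    row.names = NULL
  )
  if (!is.null(bed)) {
    rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
      iv <- covered_intervals(reports[[i]])
      if (nrow(iv) == 0) return(NULL)
      cbind(record = out$record[i], iv)
    }))
    if (is.null(rows)) rows <- data.frame(record = character(0), start = integer(0), end = integer(0))
    utils::write.table(rows, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  out
}
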
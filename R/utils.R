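# Internal helpers: classed conditions, seeded sub-streams, base-string utilities.

#' @keywords internal
#' @noRd
abort_restaple <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "restaple_error")))
}

# Derive a per-draw seed from a master seed and a draw index so that library
# draws are independent sub-streams, reorderable without changing results.
# Kept strictly below 2^31 - 1.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.double(index) * 16807) %% 2147483629) + 1L
}

DNA_BASES <- c("A", "C", "G", "T")

#' @keywords internal
#' @noRd
check_acgt <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0) {
    abort_restaple(
      sprintf("%s contains a non-ACGT character at offset %d", what, bad),
      "restaple_input_error"
    )
  }
  invisible(x)
}

# Watson-Crick complement of a base string (kept as a one-liner on purpose:
# complementarity is the core contract of scaffold derivation and is checked
# against an independent Biostrings route in the tests).
#' @keywords internal
#' @noRd
complement_bases <- function(x) chartr("ACGT", "TGCA", x)

#' @keywords internal
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_bases(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' @noRd
split_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# caDNAno-style staple colour palette (decimal RGB ints), recycled per group.
#' @keywords internal
#' @noRd
group_colors <- function(k) {
  pal <- c(13369344L, 16204552L, 16225054L, 11184640L, 5749504L, 29184L,
           243362L, 1507550L, 7536862L, 12060012L, 3355443L, 8947848L)
  rep_len(pal, k)
}
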
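# Independent oracles. These deliberately avoid the implementation's code
# paths: repeat coverage by brute-force all-pairs window comparison, and
# complementarity by walking every design cell with Biostrings doing the
# base-pairing.

# O(L^2) all-pairs repeat coverage: every window is string-compared against
# every other; positions of any window with an equal partner are unioned.
oracle_repeat_coverage <- function(seq, window) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < window) return(list(coverage_fraction = 0, duplicated_window_count = 0L))
  n <- L - window + 1L
  w <- substring(seq, seq_len(n), seq_len(n) + window - 1L)
  counts <- rowSums(outer(w, w, "=="))
  dup <- counts >= 2
  mask <- rep(FALSE, L)
  for (i in which(dup)) mask[i:(i + window - 1L)] <- TRUE
  list(coverage_fraction = sum(mask) / L,
       duplicated_window_count = sum(dup))
}

# Re-hybridisation oracle: for every staple of a candidate, pair each of its
# cells against the scaffold base at the same (helix, idx) and demand a
# Watson-Crick match everywhere. Base pairing goes through
# Biostrings::complement, independent of the package's chartr route.
oracle_rehybridize <- function(candidate) {
  scaf_pos <- candidate$scaffold_path$positions
  scaf_key <- scaf_pos[, 1] * 1e6 + scaf_pos[, 2]
  scaf_base <- strsplit(candidate$scaffold$bases, "")[[1]]
  layout <- candidate$layout
  seqs <- candidate$sequences$sequences
  total <- 0L
  matched <- 0L
  for (i in seq_along(layout$staples)) {
    st <- layout$staples[[i]]
    sq <- seqs[layout$group_of[i]]
    comp <- strsplit(as.character(Biostrings::complement(Biostrings::DNAString(sq))), "")[[1]]
    pos <- st$path$positions
    at <- match(pos[, 1] * 1e6 + pos[, 2], scaf_key)
    stopifnot(!anyNA(at))
    total <- total + length(at)
    matched <- matched + sum(scaf_base[at] == comp)
  }
  list(total = total, matched = matched, fraction = matched / total)
}

# Literal recount of helix-change adjacencies over a set of paths.
oracle_count_crossovers <- function(paths) {
  n <- 0L
  for (p in paths) {
    h <- p$positions[, 1]
    if (length(h) < 2) next
    for (j in 2:length(h)) if (h[j] != h[j - 1]) n <- n + 1L
  }
  n
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Minimal hand-built staple for grouping unit tests (no design behind it).
fake_staple <- function(len, helix = 0L, start = 0L, source_path = 1L, offset = 1L) {
  len <- as.integer(len)
  path <- structure(list(
    kind = "staple",
    positions = cbind(helix, start:(start + len - 1L)),
    circular = FALSE
  ), class = "strand_path")
  structure(list(path = path, length = len, signature = integer(0),
                 source_path = source_path, offset = offset),
            class = "staple")
}

fake_path <- function(len, helix = 0L) {
  structure(list(kind = "staple", positions = cbind(helix, 0:(len - 1L)),
                 circular = FALSE), class = "strand_path")
}
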
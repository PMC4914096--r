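# Synthetic caDNAno designs: raster-routed helix bundles (toy duplex through
# 24-helix bundle) and adversarial degenerate files, so every operation is
# testable without external design files.

#' Generate a synthetic helix-bundle caDNAno design
#'
#' Emits a connected design of `n_helices` parallel helices with one scaffold
#' strand and unbroken staple paths, following the caDNAno parity convention
#' (even helices: scaffold 5'->3' in increasing base index, staples
#' decreasing; odd helices the reverse).
#'
#' Routing is a simplified raster with crossovers at every permitted
#' position, emulating a high-crossover-density bundle. The scaffold runs the
#' full length of helix 0, then covers the remaining helices in a vertical
#' boustrophedon whose column blocks are `3 * xover_spacing` wide (21-nt
#' scaffold runs between crossovers at the honeycomb raster of 7). Staples
#' are unbroken vertical serpentines in column blocks `xover_spacing` wide
#' (7-nt staple runs), one path per block. On the 24-helix, ~6-kb bundle this
#' gives 1,093 helix-change adjacencies (181 per 1,000 scaffold nucleotides
#' counting each crossover once per strand path). Two-helix designs use a
#' single end-bend staple path and a plain scaffold serpentine (one crossover
#' each).
#'
#' The per-helix used length is the multiple of `2 * xover_spacing` nearest
#' to `scaffold_length / n_helices`; the traced scaffold length is required
#' to fall within 2% of the requested `scaffold_length`.
#'
#' @param n_helices Even number of helices (>= 2).
#' @param scaffold_length Approximate target scaffold length in nt.
#' @param lattice "honeycomb" or "square".
#' @param xover_spacing Raster unit in nt between permitted crossover
#'   positions; defaults to 7 (honeycomb) or 16 (square).
#' @return A `cadnano_design` that passes [parse_cadnano()] validation.
#' @export
make_helix_bundle <- function(n_helices, scaffold_length,
                              lattice = c("honeycomb", "square"),
                              xover_spacing = NULL) {
  lattice <- match.arg(lattice)
  n <- as.integer(n_helices)
  if (is.na(n) || n < 2 || n %% 2 != 0) {
    abort_restaple("n_helices must be an even integer >= 2", "restaple_fixture_error")
  }
  if (scaffold_length < n * 8) {
    abort_restaple("scaffold_length must be at least 8 nt per helix",
                   "restaple_fixture_error")
  }
  s <- if (is.null(xover_spacing)) {
    if (lattice == "honeycomb") 7L else 16L
  } else {
    as.integer(xover_spacing)
  }
  if (is.na(s) || s < 2) {
    abort_restaple("xover_spacing must be an integer >= 2", "restaple_fixture_error")
  }
  unit <- 2L * s
  L <- as.integer(round(scaffold_length / n / unit)) * unit
  if (L < unit) L <- unit
  if (abs(n * L - scaffold_length) > 0.02 * scaffold_length) {
    abort_restaple(
      sprintf("no raster of %d helices at spacing %d lands within 2%% of %d nt (closest: %d)",
              n, s, as.integer(scaffold_length), n * L),
      "restaple_fixture_error"
    )
  }
  lat_unit <- if (lattice == "honeycomb") 21L else 32L
  arr_len <- (L %/% lat_unit + 1L) * lat_unit

  scaf_path <- scaffold_raster(n, L, 3L * s)
  stap_paths <- staple_raster(n, L, s)

  helices <- lapply(seq_len(n) - 1L, function(num) {
    list(
      num = num, row = 0L, col = num,
      scaf = matrix(CADNANO_SENTINEL, nrow = arr_len, ncol = 4),
      stap = matrix(CADNANO_SENTINEL, nrow = arr_len, ncol = 4),
      skip = rep(0L, arr_len), loop = rep(0L, arr_len),
      stap_colors = matrix(integer(0), ncol = 2)
    )
  })
  helices <- link_path(helices, scaf_path, "scaf")
  cols <- group_colors(length(stap_paths))
  for (i in seq_along(stap_paths)) {
    helices <- link_path(helices, stap_paths[[i]], "stap")
    h5 <- stap_paths[[i]][1, 1] + 1L
    helices[[h5]]$stap_colors <- rbind(helices[[h5]]$stap_colors,
                                       c(stap_paths[[i]][1, 2], cols[i]))
  }
  for (i in seq_along(helices)) {
    sc <- helices[[i]]$stap_colors
    if (nrow(sc) > 1) sc <- sc[order(sc[, 1]), , drop = FALSE]
    dimnames(sc) <- NULL
    storage.mode(sc) <- "integer"
    helices[[i]]$stap_colors <- sc
  }

  structure(list(
    name = sprintf("bundle_%dhx_%dnt_%s", n, n * L, lattice),
    lattice = lattice,
    helices = helices
  ), class = "cadnano_design")
}

# Write mutual 5'/3' pointers for a path of (helix num, idx) rows.
#' @keywords internal
#' @noRd
link_path <- function(helices, pos, kind) {
  m <- nrow(pos)
  for (j in seq_len(m - 1L)) {
    a <- pos[j, ]; b <- pos[j + 1L, ]
    helices[[a[1] + 1L]][[kind]][a[2] + 1L, c(3L, 4L)] <- b
    helices[[b[1] + 1L]][[kind]][b[2] + 1L, c(1L, 2L)] <- a
  }
  helices
}

# Column-leg helper: (helix, from..to) as a 2-column matrix of 0-based cells.
#' @keywords internal
#' @noRd
leg <- function(h, from, to) cbind(h, from:to)

# Scaffold raster: helix-0 rail plus a right-to-left vertical boustrophedon
# over helices 1..n-1 in blocks `width` columns wide (last block partial).
# Even helices run 5'->3' in increasing idx, odd helices decreasing.
#' @keywords internal
#' @noRd
scaffold_raster <- function(n, L, width) {
  if (n == 2) {
    return(rbind(leg(0L, 0L, L - 1L), leg(1L, L - 1L, 0L)))
  }
  out <- list(leg(0L, 0L, L - 1L))
  hi <- L - 1L
  j <- 0L
  while (hi >= 0L) {
    lo <- max(hi - width + 1L, 0L)
    hs <- if (j %% 2L == 0L) seq(1L, n - 1L) else seq(n - 1L, 1L)
    for (h in hs) {
      out[[length(out) + 1L]] <- if (h %% 2L == 1L) leg(h, hi, lo) else leg(h, lo, hi)
    }
    hi <- lo - 1L
    j <- j + 1L
  }
  do.call(rbind, out)
}

# Staple raster: one unbroken vertical serpentine per `width`-column block
# covering all helices (even helices decreasing, odd increasing); a 2-helix
# design collapses to a single end-bend path.
#' @keywords internal
#' @noRd
staple_raster <- function(n, L, width) {
  if (n == 2) {
    return(list(rbind(leg(0L, L - 1L, 0L), leg(1L, 0L, L - 1L))))
  }
  paths <- list()
  lo <- 0L
  while (lo < L) {
    hi <- min(lo + width - 1L, L - 1L)
    out <- lapply(seq_len(n) - 1L, function(h) {
      if (h %% 2L == 0L) leg(h, hi, lo) else leg(h, lo, hi)
    })
    paths[[length(paths) + 1L]] <- do.call(rbind, out)
    lo <- hi + 1L
  }
  paths
}

#' Adversarial caDNAno files for error-path testing
#'
#' Each named JSON text triggers one specific failure: `dangling_pointer`
#' (linkage error at parse), `two_scaffolds` (topology error when tracing),
#' `loop_insertion` (unsupported-feature error) and `empty_vstrands` (schema
#' error).
#'
#' @return Named list of JSON strings.
#' @export
make_degenerate_cases <- function() {
  base <- make_helix_bundle(2, 64, "square", 16)

  dangling <- base
  dangling$helices[[1]]$scaf[11, c(3, 4)] <- c(9L, 3L) # helix 9 does not exist

  two <- base
  L <- 32L
  two$helices[[1]]$scaf[L, c(3, 4)] <- c(CADNANO_SENTINEL, CADNANO_SENTINEL)
  two$helices[[2]]$scaf[L, c(1, 2)] <- c(CADNANO_SENTINEL, CADNANO_SENTINEL)

  loopy <- base
  loopy$helices[[1]]$loop[7] <- 1L

  list(
    dangling_pointer = format_cadnano(dangling),
    two_scaffolds = format_cadnano(two),
    loop_insertion = format_cadnano(loopy),
    empty_vstrands = '{"name":"empty","vstrands":[]}'
  )
}
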
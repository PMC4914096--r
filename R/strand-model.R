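# Tracing scaffold and staple strand paths and computing design metrics.
#
# A strand path ("strand_path") is a list:
#   kind      - "scaffold" or "staple"
#   positions - m x 2 integer matrix of (helix num, base idx), 5' -> 3'
#   circular  - TRUE when the strand closes on itself
# Positions exclude skip = -1 cells; crossing to another helix between two
# consecutive positions is a crossover.

#' @keywords internal
#' @noRd
new_strand_path <- function(kind, positions, circular = FALSE) {
  structure(list(kind = kind, positions = positions, circular = circular),
            class = "strand_path")
}

#' @export
print.strand_path <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("%s path: %d nt%s, %d crossover(s), 5' at helix %d idx %d\n",
              x$kind, n, if (x$circular) " (circular)" else "",
              length(crossover_offsets(x)), x$positions[1, 1], x$positions[1, 2]))
  invisible(x)
}

#' @export
length.strand_path <- function(x) nrow(x$positions)

# Trace all components of one strand kind through the design linkage.
#' @keywords internal
#' @noRd
trace_components <- function(design, kind) {
  nums <- vapply(design$helices, function(h) h$num, integer(1))
  idx_of <- stats::setNames(seq_along(nums), nums)
  mats <- lapply(design$helices, `[[`, kind)
  skips <- lapply(design$helices, `[[`, "skip")
  n <- nrow(mats[[1]])

  used <- lapply(mats, function(m) rowSums(m != CADNANO_SENTINEL) > 0)
  visited <- lapply(used, function(u) rep(FALSE, length(u)))

  walk <- function(hi, i) {
    # follow 3' pointers from (hi, i); returns matrix of (helix num, idx)
    cap <- sum(vapply(used, sum, integer(1)))
    out <- matrix(NA_integer_, nrow = cap, ncol = 2)
    len <- 0L
    repeat {
      if (visited[[hi]][i]) break
      visited[[hi]][i] <<- TRUE
      if (skips[[hi]][i] == 0L) {
        len <- len + 1L
        out[len, ] <- c(nums[hi], i - 1L)
      }
      nh <- mats[[hi]][i, 3L]; ni <- mats[[hi]][i, 4L]
      if (nh == CADNANO_SENTINEL) break
      hi <- idx_of[[as.character(nh)]]
      i <- ni + 1L
    }
    out[seq_len(len), , drop = FALSE]
  }

  paths <- list()
  # linear components start at a 5' terminus (used cell with sentinel 5' side)
  for (hi in seq_along(mats)) {
    starts <- which(used[[hi]] & mats[[hi]][, 1L] == CADNANO_SENTINEL)
    for (i in starts) {
      if (!visited[[hi]][i]) {
        paths[[length(paths) + 1L]] <- new_strand_path(
          if (kind == "scaf") "scaffold" else "staple", walk(hi, i), circular = FALSE
        )
      }
    }
  }
  # remaining used cells belong to circular components; start each at its
  # lowest (helix num, idx)
  ord <- order(nums)
  for (hi in ord) {
    repeat {
      left <- which(used[[hi]] & !visited[[hi]])
      if (length(left) == 0) break
      paths[[length(paths) + 1L]] <- new_strand_path(
        if (kind == "scaf") "scaffold" else "staple", walk(hi, left[1]), circular = TRUE
      )
    }
  }
  paths
}

#' Trace the scaffold strand of a design
#'
#' Follows the scaffold linkage 5' to 3'. The design must contain exactly one
#' connected scaffold component; a closed scaffold is returned with
#' `circular = TRUE`, starting at its lowest (helix num, idx) position.
#' Skipped cells (`skip = -1`) are omitted from the path.
#'
#' @param design A `cadnano_design`.
#' @return A `strand_path` of kind "scaffold".
#' @export
trace_scaffold <- function(design) {
  stopifnot(inherits(design, "cadnano_design"))
  comps <- trace_components(design, "scaf")
  if (length(comps) != 1) {
    abort_restaple(
      sprintf("design must contain exactly one scaffold component, found %d", length(comps)),
      "restaple_topology_error", count = length(comps)
    )
  }
  comps[[1]]
}

#' Trace all staple strands of a design
#'
#' Returns one path per staple 5' terminus plus any circular staple
#' components. Together the paths cover every staple-occupied, non-skipped
#' cell exactly once.
#'
#' @param design A `cadnano_design`.
#' @return A list of `strand_path` objects of kind "staple" (possibly empty).
#' @export
trace_staples <- function(design) {
  stopifnot(inherits(design, "cadnano_design"))
  trace_components(design, "stap")
}

#' Within-strand crossover offsets of a path
#'
#' Offsets `o` (0-based, `1 <= o < length`) at which the path changes helix
#' between positions `o - 1` and `o`; the offset list is the staple's
#' crossover-arrangement signature. Two staples bind their template with the
#' same arrangement exactly when their signatures are equal.
#'
#' @param path A `strand_path`.
#' @return Integer vector of offsets (empty when the path stays on one helix).
#' @export
crossover_offsets <- function(path) {
  stopifnot(inherits(path, "strand_path"))
  h <- path$positions[, 1]
  n <- length(h)
  if (n < 2) return(integer(0))
  which(h[-1] != h[-n])
}

#' @keywords internal
#' @noRd
count_crossovers <- function(paths) {
  sum(vapply(paths, function(p) length(crossover_offsets(p)), integer(1)))
}

#' Design metrics: lengths, counts and crossover density
#'
#' Counts every helix-change adjacency once per strand path (so a double
#' crossover counts twice, once per strand) and normalises the total per
#' 1,000 scaffold nucleotides. When a staple layout is supplied, staple
#' counts and binding-multiplicity statistics (template locations per unique
#' sequence) are computed from its grouping; otherwise the unbroken staple
#' routing is measured.
#'
#' @param design A `cadnano_design`.
#' @param layout Optional `staple_layout` consistent with the design.
#' @return A `design_metrics` list: `scaffold_length`, `staple_count`,
#'   `unique_count`, `multiplicity_mean`, `multiplicity_sd`,
#'   `staple_len_min`, `staple_len_max`, `scaffold_xovers`, `staple_xovers`,
#'   `xover_density`.
#' @export
design_metrics <- function(design, layout = NULL) {
  stopifnot(inherits(design, "cadnano_design"))
  scaf <- trace_scaffold(design)
  scaffold_length <- nrow(scaf$positions)
  scaffold_xovers <- length(crossover_offsets(scaf))

  if (is.null(layout)) {
    spaths <- trace_staples(design)
    staple_count <- length(spaths)
    unique_count <- NA_integer_
    mult_mean <- NA_real_
    mult_sd <- NA_real_
  } else {
    stopifnot(inherits(layout, "staple_layout"))
    design_cells <- staple_cell_keys(trace_staples(design))
    layout_cells <- staple_cell_keys(lapply(layout$staples, `[[`, "path"))
    if (!setequal(design_cells, layout_cells) ||
        length(layout_cells) != length(design_cells)) {
      abort_restaple("layout does not tile the design's staple-occupied cells",
                     "restaple_consistency_error")
    }
    spaths <- lapply(layout$staples, `[[`, "path")
    staple_count <- length(layout$staples)
    unique_count <- layout$k
    sizes <- tabulate(layout$group_of, nbins = layout$k)
    mult_mean <- staple_count / unique_count
    mult_sd <- stats::sd(sizes)
  }
  staple_xovers <- count_crossovers(spaths)
  lens <- vapply(spaths, function(p) nrow(p$positions), integer(1))

  structure(list(
    scaffold_length = scaffold_length,
    staple_count = staple_count,
    unique_count = unique_count,
    multiplicity_mean = mult_mean,
    multiplicity_sd = mult_sd,
    staple_len_min = if (length(lens)) min(lens) else NA_integer_,
    staple_len_max = if (length(lens)) max(lens) else NA_integer_,
    scaffold_xovers = scaffold_xovers,
    staple_xovers = staple_xovers,
    xover_density = 1000 * (scaffold_xovers + staple_xovers) / scaffold_length
  ), class = "design_metrics")
}

#' @keywords internal
#' @noRd
staple_cell_keys <- function(paths) {
  unlist(lapply(paths, function(p) p$positions[, 1] * 2^16 + p$positions[, 2]),
         use.names = FALSE)
}

#' @export
print.design_metrics <- function(x, ...) {
  cat(sprintf("scaffold: %d nt, %d scaffold + %d staple crossovers (%.2f per 1,000 nt)\n",
              x$scaffold_length, x$scaffold_xovers, x$staple_xovers, x$xover_density))
  if (is.na(x$unique_count)) {
    cat(sprintf("unbroken staple paths: %d, lengths %d-%d nt\n",
                x$staple_count, x$staple_len_min, x$staple_len_max))
  } else {
    cat(sprintf("staples: %d in %d sequence groups (%.1f +/- %.1f binding locations), lengths %d-%d nt\n",
                x$staple_count, x$unique_count, x$multiplicity_mean,
                x$multiplicity_sd, x$staple_len_min, x$staple_len_max))
  }
  invisible(x)
}

#' @export
as.data.frame.design_metrics <- function(x, ...) {
  data.frame(
    scaffold_length = x$scaffold_length, staple_count = x$staple_count,
    unique_count = x$unique_count, multiplicity_mean = x$multiplicity_mean,
    multiplicity_sd = x$multiplicity_sd, staple_len_min = x$staple_len_min,
    staple_len_max = x$staple_len_max, scaffold_xovers = x$scaffold_xovers,
    staple_xovers = x$staple_xovers, xover_density = x$xover_density
  )
}
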
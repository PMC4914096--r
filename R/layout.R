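# Random segmentation of the unbroken staple routing into staples, and
# grouping of staples into k length-homogeneous sequence classes.

LENGTH_PRESETS <- list(
  short  = c(25L, 62L),   # "short" staples
  long   = c(60L, 125L),  # "long" staples
  bundle = c(38L, 77L)    # 24-helix-bundle staple lengths
)

#' Search configuration for custom-scaffold design
#'
#' Bundles every tunable parameter of the layout search. Length bounds can be
#' set directly or through a named preset: `"short"` (25-62 nt), `"long"`
#' (60-125 nt) or `"bundle"` (38-77 nt).
#'
#' @param k_unique Number of unique staple sequences (e.g. 10, 15 or 20).
#' @param iterations Library size: number of independent candidate draws.
#' @param n_best Number of top-ranked designs reported by print/summary.
#' @param preset Optional length preset name (overrides `len_min`/`len_max`).
#' @param len_min,len_max Inclusive staple length bounds in nt.
#' @param window Minimum repeat length in nt for repetitiveness scoring.
#' @param seed Integer master seed; per-draw sub-streams are derived from it.
#' @param sequences Optional character vector of predefined staple sequences,
#'   used verbatim instead of random sequences.
#' @param gc_min,gc_max Optional GC-fraction bounds for random sequences.
#' @param forbidden_motifs Motifs screened (advisory, never a hard failure)
#'   in derived scaffolds; defaults to the BtsCI recognition site and its
#'   reverse complement.
#' @param multiplicity_tol Allowed deviation of group sizes from the balanced
#'   value `staple_count / k_unique`.
#' @param repetitive_arrangement When TRUE, all unbroken paths of equal length
#'   are cut with one shared pattern, forcing identical crossover-arrangement
#'   signatures across corresponding staples (the repetitive-arrangement
#'   condition known to depress folding yield).
#' @return A validated `design_config` object.
#' @export
design_config <- function(k_unique,
                          iterations = 100L,
                          n_best = 1L,
                          preset = NULL,
                          len_min = 38L,
                          len_max = 77L,
                          window = 12L,
                          seed = 1L,
                          sequences = NULL,
                          gc_min = NULL,
                          gc_max = NULL,
                          forbidden_motifs = c("GGATG", "CATCC"),
                          multiplicity_tol = 2L,
                          repetitive_arrangement = FALSE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(LENGTH_PRESETS))
    len_min <- LENGTH_PRESETS[[preset]][1]
    len_max <- LENGTH_PRESETS[[preset]][2]
  }
  k_unique <- as.integer(k_unique)
  iterations <- as.integer(iterations)
  n_best <- as.integer(n_best)
  len_min <- as.integer(len_min)
  len_max <- as.integer(len_max)
  window <- as.integer(window)
  seed <- as.integer(seed)
  if (is.na(k_unique) || k_unique < 1) {
    abort_restaple("k_unique must be >= 1", "restaple_argument_error")
  }
  if (len_min > len_max || len_min < 1) {
    abort_restaple("need 1 <= len_min <= len_max", "restaple_argument_error")
  }
  if (window < 2) abort_restaple("window must be >= 2", "restaple_argument_error")
  if (iterations < 1) abort_restaple("iterations must be >= 1", "restaple_argument_error")
  if (n_best > iterations) {
    abort_restaple("n_best cannot exceed iterations", "restaple_argument_error")
  }
  if (!is.null(sequences)) {
    sequences <- toupper(as.character(sequences))
    for (s in sequences) check_acgt(s, "predefined staple sequence")
  }
  if (!is.null(gc_min) || !is.null(gc_max)) {
    gc_min <- if (is.null(gc_min)) 0 else as.numeric(gc_min)
    gc_max <- if (is.null(gc_max)) 1 else as.numeric(gc_max)
    if (gc_min < 0 || gc_max > 1 || gc_min > gc_max) {
      abort_restaple("need 0 <= gc_min <= gc_max <= 1", "restaple_argument_error")
    }
  }
  structure(list(
    k_unique = k_unique, iterations = iterations, n_best = n_best,
    preset = preset, len_min = len_min, len_max = len_max, window = window,
    seed = seed, sequences = sequences, gc_min = gc_min, gc_max = gc_max,
    forbidden_motifs = forbidden_motifs,
    multiplicity_tol = as.integer(multiplicity_tol),
    repetitive_arrangement = isTRUE(repetitive_arrangement)
  ), class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    "design_config: k_unique = %d, iterations = %d, staple lengths %d-%d nt%s,\n  window = %d nt, seed = %d, sequences = %s, multiplicity_tol = %d%s\n",
    x$k_unique, x$iterations, x$len_min, x$len_max,
    if (!is.null(x$preset)) sprintf(" (preset \"%s\")", x$preset) else "",
    x$window, x$seed,
    if (is.null(x$sequences)) "random" else sprintf("%d predefined", length(x$sequences)),
    x$multiplicity_tol,
    if (x$repetitive_arrangement) ", repetitive staple crossover arrangement" else ""
  ))
  invisible(x)
}

# Subset a strand path to positions [from, to] (1-based along the path).
#' @keywords internal
#' @noRd
slice_path <- function(path, from, to) {
  new_strand_path(path$kind, path$positions[from:to, , drop = FALSE], FALSE)
}

#' @keywords internal
#' @noRd
new_staple <- function(path, source_path, offset) {
  structure(list(
    path = path,
    length = nrow(path$positions),
    signature = crossover_offsets(path),
    source_path = source_path,
    offset = offset  # 1-based start within the unbroken path
  ), class = "staple")
}

# Reachability DP: which totals 0..total are sums of palette lengths.
#' @keywords internal
#' @noRd
palette_reachable <- function(total, palette) {
  reach <- c(TRUE, rep(FALSE, total))
  for (t in seq_len(total)) {
    for (p in palette) {
      if (t >= p && reach[t - p + 1L]) { reach[t + 1L] <- TRUE; break }
    }
  }
  reach
}

# Random exact partition of `total` into palette parts, sampled by a random
# walk on the reachability DP (every prefix stays completable). Among the
# feasible lengths the least-used one is taken (random tie-break), so palette
# lengths are consumed evenly across the whole design and the k sequence
# groups can be kept near the balanced multiplicity.
#' @keywords internal
#' @noRd
sample_partition <- function(total, palette, reach, usage) {
  parts <- integer(0)
  t <- total
  while (t > 0) {
    cand <- palette[palette <= t]
    ok <- cand[reach[t - cand + 1L]]
    u <- usage[match(ok, palette)]
    ok <- ok[u == min(u)]
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    usage[match(pick, palette)] <- usage[match(pick, palette)] + 1L
    parts <- c(parts, pick)
    t <- t - pick
  }
  list(parts = parts, usage = usage)
}

#' Randomly segment unbroken staple paths into staples
#'
#' Draws a palette of at most `k_unique` distinct lengths within
#' `[len_min, len_max]` and cuts every unbroken path into consecutive staples
#' whose lengths come from that palette, partitioning each path exactly.
#' Palettes that cannot partition every path are re-drawn up to `budget`
#' times. With `config$repetitive_arrangement`, paths of equal length share
#' one cut pattern so that corresponding staples carry identical
#' crossover-arrangement signatures.
#'
#' Randomness is taken from R's global RNG stream; seed it (or let
#' [run_search()] seed it per draw) for reproducible layouts.
#'
#' @param paths List of unbroken `strand_path`s (from [trace_staples()]).
#' @param config A `design_config`.
#' @param budget Palette retry budget.
#' @return List of `staple` objects, in path order.
#' @export
segment_paths <- function(paths, config, budget = 100L) {
  stopifnot(inherits(config, "design_config"))
  if (length(paths) == 0) return(list())
  totals <- vapply(paths, function(p) nrow(p$positions), integer(1))
  if (any(totals < config$len_min)) {
    abort_restaple(
      sprintf("unbroken path %d (%d nt) is shorter than len_min = %d",
              which(totals < config$len_min)[1],
              min(totals), config$len_min),
      "restaple_infeasible_error"
    )
  }
  lens_avail <- config$len_min:config$len_max
  n_pal <- min(config$k_unique, length(lens_avail))

  for (try in seq_len(budget)) {
    palette <- sort(lens_avail[sample.int(length(lens_avail), n_pal)])
    reaches <- lapply(sort(unique(totals)), function(t) palette_reachable(t, palette))
    names(reaches) <- sort(unique(totals))
    if (!all(vapply(reaches, function(r) r[length(r)], logical(1)))) next

    shared <- list() # per distinct total, the shared cut pattern (repetitive mode)
    staples <- list()
    usage <- integer(length(palette))
    for (pi in seq_along(paths)) {
      t <- totals[pi]
      key <- as.character(t)
      parts <- if (config$repetitive_arrangement && !is.null(shared[[key]])) {
        shared[[key]]
      } else {
        sp <- sample_partition(t, palette, reaches[[key]], usage)
        usage <- sp$usage
        if (config$repetitive_arrangement) shared[[key]] <- sp$parts
        sp$parts
      }
      at <- 1L
      for (len in parts) {
        staples[[length(staples) + 1L]] <-
          new_staple(slice_path(paths[[pi]], at, at + len - 1L), pi, at)
        at <- at + len
      }
    }
    return(staples)
  }
  abort_restaple(
    sprintf("no palette of %d lengths in [%d, %d] partitions all paths (lengths %s) after %d tries",
            n_pal, config$len_min, config$len_max,
            paste(sort(unique(totals)), collapse = ", "), budget),
    "restaple_infeasible_error"
  )
}

# Minimax allocation of k groups across distinct lengths: repeatedly grant an
# extra group to the length with the largest current per-group size.
#' @keywords internal
#' @noRd
allocate_groups <- function(counts, k) {
  g <- rep(1L, length(counts))
  while (sum(g) < k) {
    open <- which(g < counts) # a group must stay non-empty
    if (length(open) == 0) break
    pick <- open[which.max(counts[open] / g[open])]
    g[pick] <- g[pick] + 1L
  }
  g
}

#' Group staples into k length-homogeneous sequence classes
#'
#' Partitions the staples into exactly `k_unique` non-empty groups, each
#' containing staples of a single length, so that one sequence per group can
#' be reused at every binding location. Group membership among equal-length
#' staples is randomised (seeded stream), and group sizes are kept as close
#' to the balanced value `length(staples) / k_unique` as the length multiset
#' allows.
#'
#' @param staples List of `staple` objects (from [segment_paths()]).
#' @param config A `design_config`.
#' @param paths The unbroken paths the staples were cut from (kept on the
#'   layout for partition-exactness validation); optional.
#' @return A `staple_layout`: `staples`, `group_of` (integer in 1..k),
#'   `k`, `paths`.
#' @export
assign_groups <- function(staples, config, paths = NULL) {
  stopifnot(inherits(config, "design_config"))
  k <- config$k_unique
  n <- length(staples)
  if (n < k) {
    abort_restaple(sprintf("%d staples cannot form %d groups", n, k),
                   "restaple_infeasible_error")
  }
  lens <- vapply(staples, `[[`, integer(1), "length")
  tab <- table(lens)
  if (length(tab) > k) {
    abort_restaple(
      sprintf("%d distinct staple lengths admit no %d-group length-homogeneous partition",
              length(tab), k),
      "restaple_infeasible_error"
    )
  }
  counts <- as.integer(tab)
  g_per_len <- allocate_groups(counts, k)
  if (sum(g_per_len) != k) {
    abort_restaple("staple length multiset admits no k-group partition",
                   "restaple_infeasible_error")
  }

  group_of <- integer(n)
  gid <- 0L
  for (li in seq_along(tab)) {
    idx <- which(lens == as.integer(names(tab)[li]))
    idx <- idx[sample.int(length(idx))]              # randomise membership
    chunks <- split(idx, sort(rep_len(seq_len(g_per_len[li]), length(idx))))
    for (ch in chunks) {
      gid <- gid + 1L
      group_of[ch] <- gid
    }
  }
  structure(list(staples = staples, group_of = group_of, k = k, paths = paths),
            class = "staple_layout")
}

#' @export
print.staple_layout <- function(x, ...) {
  sizes <- tabulate(x$group_of, nbins = x$k)
  lens <- vapply(x$staples, `[[`, integer(1), "length")
  cat(sprintf(
    "staple layout: %d staples in %d groups (sizes %d-%d), lengths %d-%d nt\n",
    length(x$staples), x$k, min(sizes), max(sizes), min(lens), max(lens)
  ))
  invisible(x)
}

#' Check a staple layout against its configuration
#'
#' Violations are returned as data, not raised: staple lengths outside
#' `[len_min, len_max]`, groups mixing lengths, group sizes outside the
#' multiplicity tolerance, and (when the layout records its source paths)
#' staples failing to tile each unbroken path exactly.
#'
#' @param layout A `staple_layout`.
#' @param config A `design_config`.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_layout <- function(layout, config) {
  stopifnot(inherits(layout, "staple_layout"), inherits(config, "design_config"))
  v <- character(0)
  lens <- vapply(layout$staples, `[[`, integer(1), "length")
  bad <- which(lens < config$len_min | lens > config$len_max)
  for (i in bad) {
    v <- c(v, sprintf("staple %d length %d outside [%d, %d]",
                      i, lens[i], config$len_min, config$len_max))
  }
  for (g in seq_len(layout$k)) {
    gl <- unique(lens[layout$group_of == g])
    if (length(gl) == 0) {
      v <- c(v, sprintf("group %d is empty", g))
    } else if (length(gl) > 1) {
      v <- c(v, sprintf("group %d mixes staple lengths %s",
                        g, paste(gl, collapse = ", ")))
    }
  }
  sizes <- tabulate(layout$group_of, nbins = layout$k)
  bal <- length(layout$staples) / layout$k
  off <- which(abs(sizes - bal) > config$multiplicity_tol)
  for (g in off) {
    v <- c(v, sprintf("group %d size %d deviates from balanced %.1f by more than %d",
                      g, sizes[g], bal, config$multiplicity_tol))
  }
  if (!is.null(layout$paths)) {
    for (pi in seq_along(layout$paths)) {
      st <- layout$staples[vapply(layout$staples, `[[`, integer(1), "source_path") == pi]
      offs <- vapply(st, `[[`, integer(1), "offset")
      o <- order(offs)
      covered <- unlist(lapply(st[o], function(s) seq(s$offset, length.out = s$length)))
      want <- seq_len(nrow(layout$paths[[pi]]$positions))
      if (!identical(as.integer(covered), as.integer(want))) {
        v <- c(v, sprintf("staples do not exactly tile unbroken path %d", pi))
      }
    }
  }
  v
}

# One full layout draw: segmentation + grouping, resampled until the group
# sizes sit within the multiplicity tolerance (or the budget is exhausted).
#' @keywords internal
#' @noRd
propose_layout <- function(paths, config, budget = 50L) {
  last_dev <- NA_real_
  for (try in seq_len(budget)) {
    staples <- segment_paths(paths, config)
    if (length(staples) < config$k_unique) next
    layout <- tryCatch(assign_groups(staples, config, paths = paths),
                       restaple_infeasible_error = function(e) NULL)
    if (is.null(layout)) next
    sizes <- tabulate(layout$group_of, nbins = layout$k)
    bal <- length(layout$staples) / layout$k
    last_dev <- max(abs(sizes - bal))
    if (last_dev <= config$multiplicity_tol) return(layout)
  }
  abort_restaple(
    sprintf("no layout within multiplicity tolerance %d after %d draws (last deviation %.1f)",
            config$multiplicity_tol, budget, last_dev),
    "restaple_infeasible_error"
  )
}
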
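# Library search: draw candidate (layout, sequences, scaffold) triples, score
# repetitiveness, rank, and export winners.

#' Search staple layouts for the least repetitive custom scaffold
#'
#' Runs `config$iterations` independent draws. Each draw re-segments the
#' design's unbroken staple routing into staples, groups them into
#' `k_unique` sequence classes, assigns one sequence per class, derives the
#' forced-complementary scaffold and scores its repeat coverage at
#' `config$window`. Draws use RNG sub-streams derived from `(config$seed,
#' draw index)`, so a draw's result does not depend on the other draws.
#' Candidates are ranked by ascending coverage fraction, ties broken by draw
#' index. Infeasible draws (e.g. no balanced grouping) are recorded with
#' their reasons and excluded from the ranking rather than aborting the
#' search; if every draw fails, a search error aggregates the reasons.
#'
#' @param design A `cadnano_design` with unbroken staple routing.
#' @param config A `design_config`.
#' @return A `scaffold_search` object: `candidates` (ranked list of
#'   `scaffold_candidate`), `failures` (per-draw reasons), `config`, `design`.
#' @export
run_search <- function(design, config) {
  stopifnot(inherits(design, "cadnano_design"), inherits(config, "design_config"))
  scaf_path <- trace_scaffold(design)
  unbroken <- trace_staples(design)
  if (length(unbroken) == 0) {
    abort_restaple("design has no staple routing to segment", "restaple_topology_error")
  }

  candidates <- list()
  failures <- list()
  for (i in seq_len(config$iterations)) {
    res <- tryCatch({
      set.seed(derive_seed(config$seed, i))
      layout <- propose_layout(unbroken, config)
      seqs <- assign_sequences(layout, config)
      scaffold <- derive_scaffold(scaf_path, layout, seqs)
      report <- repeat_coverage(scaffold$bases, config$window)
      metrics <- design_metrics(design, layout)
      structure(list(
        index = i, layout = layout, sequences = seqs, scaffold = scaffold,
        report = report, metrics = metrics, design = design,
        scaffold_path = scaf_path, config = config
      ), class = "scaffold_candidate")
    }, restaple_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(index = i, reason = conditionMessage(res))
    } else {
      candidates[[length(candidates) + 1L]] <- res
    }
  }
  if (length(candidates) == 0) {
    abort_restaple(
      paste0("all draws infeasible: ",
             paste(unique(vapply(failures, `[[`, character(1), "reason")), collapse = "; ")),
      "restaple_search_error"
    )
  }
  cov <- vapply(candidates, function(cd) cd$report$coverage_fraction, numeric(1))
  idx <- vapply(candidates, `[[`, integer(1), "index")
  candidates <- candidates[order(cov, idx)]

  structure(list(
    candidates = candidates,
    failures = failures,
    config = config,
    design = design
  ), class = "scaffold_search")
}

#' @export
print.scaffold_search <- function(x, ...) {
  cov <- coverage_fractions(x)
  cat(sprintf(
    "scaffold search on \"%s\": %d candidate(s) (%d infeasible draw(s)), k_unique = %d, seed = %d\n",
    x$design$name, length(x$candidates), length(x$failures),
    x$config$k_unique, x$config$seed
  ))
  n_show <- min(x$config$n_best, length(x$candidates))
  for (r in seq_len(n_show)) {
    cd <- x$candidates[[r]]
    cat(sprintf(
      "  rank %d (draw %d): repeat coverage %.1f%%, %d staples x %d groups, multiplicity %.1f +/- %.1f\n",
      r, cd$index, 100 * cd$report$coverage_fraction,
      cd$metrics$staple_count, cd$metrics$unique_count,
      cd$metrics$multiplicity_mean, cd$metrics$multiplicity_sd
    ))
  }
  invisible(x)
}

#' @export
summary.scaffold_search <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("library of %d candidates (window %d nt):\n",
              nrow(df), object$config$window))
  cat(sprintf("  coverage: best %.3f, median %.3f, worst %.3f\n",
              min(df$coverage_fraction), stats::median(df$coverage_fraction),
              max(df$coverage_fraction)))
  cat(sprintf("  staples per candidate: %d-%d, lengths %d-%d nt\n",
              min(df$staple_count), max(df$staple_count),
              min(df$staple_len_min), max(df$staple_len_max)))
  invisible(df)
}

#' Ranked coverage fractions of a search library
#' @param x A `scaffold_search`.
#' @return Numeric vector, ascending.
#' @export
coverage_fractions <- function(x) {
  stopifnot(inherits(x, "scaffold_search"))
  vapply(x$candidates, function(cd) cd$report$coverage_fraction, numeric(1))
}

#' @export
as.data.frame.scaffold_search <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$candidates), function(r) {
    cd <- x$candidates[[r]]
    cbind(data.frame(rank = r, draw = cd$index,
                     coverage_fraction = cd$report$coverage_fraction),
          as.data.frame(cd$metrics))
  }))
}

#' @export
plot.scaffold_search <- function(x, ...) {
  cov <- coverage_fractions(x)
  graphics::plot(seq_along(cov), 100 * cov, pch = 19,
                 xlab = "candidate rank", ylab = "repeat coverage (%)",
                 main = sprintf("%s: k = %d", x$design$name, x$config$k_unique), ...)
  invisible(x)
}

#' @export
print.scaffold_candidate <- function(x, ...) {
  cat(sprintf(
    "candidate (draw %d): scaffold %d nt, repeat coverage %.1f%%, %d staples in %d groups\n",
    x$index, x$scaffold$length, 100 * x$report$coverage_fraction,
    x$metrics$staple_count, x$metrics$unique_count
  ))
  invisible(x)
}

# Apply a layout's staple breaks to a design and colour staples by group.
#' @keywords internal
#' @noRd
apply_breaks <- function(design, layout) {
  nums <- vapply(design$helices, function(h) h$num, integer(1))
  hidx <- stats::setNames(seq_along(nums), nums)
  for (i in seq_along(design$helices)) {
    design$helices[[i]]$stap_colors <- matrix(integer(0), ncol = 2)
  }
  cols <- group_colors(layout$k)
  for (i in seq_along(layout$staples)) {
    st <- layout$staples[[i]]
    pos <- st$path$positions
    first <- pos[1, ]; last <- pos[nrow(pos), ]
    fh <- hidx[[as.character(first[1])]]
    lh <- hidx[[as.character(last[1])]]
    # sever the upstream link of the staple's 5' cell and the downstream link
    # of its 3' cell (and the mirrored pointers on the neighbouring cells)
    up <- design$helices[[fh]]$stap[first[2] + 1L, c(1, 2)]
    if (up[1] != CADNANO_SENTINEL) {
      design$helices[[hidx[[as.character(up[1])]]]]$stap[up[2] + 1L, c(3, 4)] <-
        c(CADNANO_SENTINEL, CADNANO_SENTINEL)
      design$helices[[fh]]$stap[first[2] + 1L, c(1, 2)] <-
        c(CADNANO_SENTINEL, CADNANO_SENTINEL)
    }
    dn <- design$helices[[lh]]$stap[last[2] + 1L, c(3, 4)]
    if (dn[1] != CADNANO_SENTINEL) {
      design$helices[[hidx[[as.character(dn[1])]]]]$stap[dn[2] + 1L, c(1, 2)] <-
        c(CADNANO_SENTINEL, CADNANO_SENTINEL)
      design$helices[[lh]]$stap[last[2] + 1L, c(3, 4)] <-
        c(CADNANO_SENTINEL, CADNANO_SENTINEL)
    }
    design$helices[[fh]]$stap_colors <- rbind(
      design$helices[[fh]]$stap_colors,
      c(first[2], cols[layout$group_of[i]])
    )
  }
  for (i in seq_along(design$helices)) {
    sc <- design$helices[[i]]$stap_colors
    if (nrow(sc) > 1) sc <- sc[order(sc[, 1]), , drop = FALSE]
    dimnames(sc) <- NULL
    storage.mode(sc) <- "integer"
    design$helices[[i]]$stap_colors <- sc
  }
  design
}

#' Export a candidate design as caDNAno JSON, FASTA, CSV and a report
#'
#' Writes, under `out_dir` with prefix `name`:
#' \describe{
#'   \item{`<name>.json`}{caDNAno v2 design with the staple breaks applied
#'     and staples coloured by sequence group.}
#'   \item{`<name>_scaffold.fa`}{the derived scaffold sequence.}
#'   \item{`<name>_staples.fa`}{one record per unique staple sequence, with
#'     group id, length and binding multiplicity in the header.}
#'   \item{`<name>_staples.csv`}{staple table: staple id, group, length,
#'     sequence, and binding location as helix:idx spans.}
#'   \item{`<name>_report.json`}{design metrics, repeat report summary and a
#'     config echo.}
#' }
#' After writing, the exported files alone are re-parsed and cross-validated
#' (every staple re-hybridised against the exported scaffold must pair
#' Watson-Crick at all positions); on failure all files are removed.
#'
#' @param candidate A `scaffold_candidate` from [run_search()].
#' @param out_dir Output directory (created if needed).
#' @param name File name prefix; defaults to the design name plus draw index.
#' @return Invisibly, the named character vector of file paths.
#' @export
export_candidate <- function(candidate, out_dir,
                             name = sprintf("%s_draw%03d", candidate$design$name, candidate$index)) {
  stopifnot(inherits(candidate, "scaffold_candidate"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort_restaple(sprintf("cannot create output directory %s", out_dir),
                   "restaple_io_error")
  }
  files <- c(
    cadnano = file.path(out_dir, paste0(name, ".json")),
    scaffold = file.path(out_dir, paste0(name, "_scaffold.fa")),
    staples = file.path(out_dir, paste0(name, "_staples.fa")),
    table = file.path(out_dir, paste0(name, "_staples.csv")),
    report = file.path(out_dir, paste0(name, "_report.json"))
  )
  layout <- candidate$layout
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  broken <- apply_breaks(candidate$design, layout)
  write_cadnano(broken, files["cadnano"])

  scaf <- Biostrings::DNAStringSet(candidate$scaffold$bases)
  names(scaf) <- sprintf("%s_scaffold length=%d coverage=%.4f window=%d",
                         name, candidate$scaffold$length,
                         candidate$report$coverage_fraction, candidate$config$window)
  Biostrings::writeXStringSet(scaf, files["scaffold"], width = 70L)

  sizes <- tabulate(layout$group_of, nbins = layout$k)
  gs <- Biostrings::DNAStringSet(candidate$sequences$sequences)
  names(gs) <- sprintf("group%02d length=%d multiplicity=%d",
                       seq_len(layout$k), nchar(candidate$sequences$sequences), sizes)
  Biostrings::writeXStringSet(gs, files["staples"], width = 70L)

  tab <- staple_table(layout, candidate$sequences)
  utils::write.csv(tab, files["table"], row.names = FALSE, quote = FALSE)

  report <- list(
    name = name,
    metrics = as.data.frame(candidate$metrics),
    coverage_fraction = candidate$report$coverage_fraction,
    duplicated_window_count = candidate$report$duplicated_window_count,
    window = candidate$config$window,
    k_unique = candidate$config$k_unique,
    seed = candidate$config$seed,
    draw = candidate$index,
    unpaired_positions = candidate$scaffold$unpaired_positions
  )
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA), files["report"])

  check <- rehybridize_exported(files["cadnano"], files["scaffold"],
                                files["staples"], files["table"])
  if (!isTRUE(check)) {
    abort_restaple(paste0("exported candidate fails cross-validation: ", check),
                   "restaple_consistency_error")
  }
  ok <- TRUE
  invisible(files)
}

#' @keywords internal
#' @noRd
staple_table <- function(layout, seqs) {
  rows <- lapply(seq_along(layout$staples), function(i) {
    st <- layout$staples[[i]]
    pos <- st$path$positions
    # contiguous helix runs as helix:first-last spans, 5'->3'
    brk <- c(0L, crossover_offsets(st$path), nrow(pos))
    spans <- vapply(seq_len(length(brk) - 1L), function(j) {
      seg <- pos[(brk[j] + 1L):brk[j + 1L], , drop = FALSE]
      sprintf("%d:%d-%d", seg[1, 1], seg[1, 2], seg[nrow(seg), 2])
    }, character(1))
    data.frame(
      staple = i,
      group = layout$group_of[i],
      length = st$length,
      sequence = seqs$sequences[layout$group_of[i]],
      binding = paste(spans, collapse = ";")
    )
  })
  do.call(rbind, rows)
}

# Cross-validation on the exported files alone: re-parse the caDNAno JSON,
# re-trace the staples, look their sequences up via the CSV table, and check
# Watson-Crick pairing against the exported scaffold at every cell.
#' @keywords internal
#' @noRd
rehybridize_exported <- function(json_file, scaffold_fa, staples_fa, table_csv) {
  design <- read_cadnano(json_file)
  scaf_path <- trace_scaffold(design)
  scaffold <- as.character(Biostrings::readDNAStringSet(scaffold_fa)[[1]])
  if (nchar(scaffold) != nrow(scaf_path$positions)) {
    return("scaffold FASTA length does not match the traced scaffold path")
  }
  groups <- as.character(Biostrings::readDNAStringSet(staples_fa))
  tab <- utils::read.csv(table_csv, stringsAsFactors = FALSE)
  staple_paths <- trace_staples(design)
  if (length(staple_paths) != nrow(tab)) {
    return(sprintf("JSON has %d staples but the table lists %d",
                   length(staple_paths), nrow(tab)))
  }
  scaf_key <- scaf_path$positions[, 1] * 2^24 + scaf_path$positions[, 2]
  scaf_base <- split_bases(scaffold)
  # map exported staple paths to table rows via their 5' position
  fivep <- vapply(staple_paths, function(p) sprintf("%d:%d", p$positions[1, 1], p$positions[1, 2]),
                  character(1))
  tab5 <- sub("-.*$", "", vapply(strsplit(tab$binding, ";"), `[[`, character(1), 1))
  m <- match(fivep, tab5)
  if (anyNA(m)) return("a traced staple has no table row")
  for (i in seq_along(staple_paths)) {
    p <- staple_paths[[i]]
    sq <- groups[tab$group[m[i]]]
    if (nchar(sq) != nrow(p$positions)) return("staple length/sequence mismatch")
    sb <- split_bases(sq)
    at <- match(p$positions[, 1] * 2^24 + p$positions[, 2], scaf_key)
    if (anyNA(at)) return("staple occupies a cell without scaffold")
    if (!all(scaf_base[at] == complement_bases(sb))) {
      return(sprintf("staple %d is not Watson-Crick complementary to the scaffold", i))
    }
  }
  TRUE
}
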
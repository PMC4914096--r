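# Reading, validating and writing caDNAno version-2 JSON designs.
#
# A design is held in memory as a list with class "cadnano_design":
#   name     - design name (text)
#   lattice  - "honeycomb" or "square", inferred from the per-helix array length
#   helices  - list of virtual helices, each a list with
#       num  - integer helix id (parity fixes strand directions)
#       row, col - lattice coordinates
#       scaf, stap - n x 4 integer matrices, one row per base position:
#                    [5'-neighbour helix, 5'-neighbour idx,
#                     3'-neighbour helix, 3'-neighbour idx], -1 = none
#       skip - integer vector (0 or -1; -1 omits the base from strand paths)
#       loop - integer vector (>= 0; insertions are rejected, see below)
#       stap_colors - m x 2 integer matrix of (idx, colour) pairs

CADNANO_SENTINEL <- -1L

#' Read a caDNAno version-2 design file
#'
#' @param file Path to a caDNAno v2 JSON file.
#' @return A validated `cadnano_design` object.
#' @seealso [parse_cadnano()], [write_cadnano()]
#' @export
read_cadnano <- function(file) {
  if (!file.exists(file)) {
    abort_restaple(sprintf("no such file: %s", file), "restaple_io_error")
  }
  parse_cadnano(paste(readLines(file, warn = FALSE), collapse = "\n"))
}

#' Parse caDNAno version-2 JSON text into a design object
#'
#' Parses the "vstrands" dialect (per-helix `scaf`/`stap` arrays of 4-tuples)
#' and validates it: every non-sentinel pointer must target an existing
#' (helix, idx) cell and pointer pairs must be mutually consistent (if cell A
#' lists B as its 3' neighbour, B must list A as its 5' neighbour). Designs
#' with loop (insertion) values > 0 are rejected as unsupported; `skip = -1`
#' cells are honoured by the path tracers. scadnano and caDNAno 2.5 files are
#' rejected with a clear message.
#'
#' @param json_text caDNAno v2 JSON as a single string.
#' @return A `cadnano_design` object.
#' @export
parse_cadnano <- function(json_text) {
  obj <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) {
      abort_restaple(paste0("malformed JSON: ", conditionMessage(e)),
                     "restaple_parse_error")
    }
  )
  if (!is.list(obj)) {
    abort_restaple("top-level JSON value is not an object", "restaple_schema_error")
  }
  if (!is.null(obj[["format"]]) || !is.null(obj[["grid"]])) {
    abort_restaple(
      "this looks like a scadnano or caDNAno 2.5 file; only caDNAno version-2 'vstrands' designs are supported",
      "restaple_schema_error"
    )
  }
  vs <- obj[["vstrands"]]
  if (is.null(vs) || length(vs) == 0) {
    abort_restaple("missing or empty \"vstrands\" array", "restaple_schema_error")
  }

  helices <- lapply(seq_along(vs), function(i) parse_vstrand(vs[[i]], i))

  lens <- vapply(helices, function(h) nrow(h$scaf), integer(1))
  if (length(unique(lens)) != 1) {
    abort_restaple("all virtual helices must share one array length",
                   "restaple_schema_error")
  }
  nums <- vapply(helices, function(h) h$num, integer(1))
  if (anyDuplicated(nums)) {
    abort_restaple("duplicate helix num in vstrands", "restaple_schema_error")
  }

  design <- structure(
    list(
      name = if (is.null(obj[["name"]])) "" else as.character(obj[["name"]]),
      lattice = infer_lattice(lens[1]),
      helices = helices
    ),
    class = "cadnano_design"
  )
  check_linkage(design)
  design
}

#' @keywords internal
#' @noRd
parse_vstrand <- function(v, i) {
  if (!is.list(v) || is.null(v[["num"]]) || is.null(v[["scaf"]]) || is.null(v[["stap"]])) {
    abort_restaple(sprintf("vstrand %d lacks num/scaf/stap", i), "restaple_schema_error")
  }
  to_mat <- function(cells, what) {
    if (length(cells) == 0) {
      abort_restaple(sprintf("vstrand %d has an empty %s array", i, what),
                     "restaple_schema_error")
    }
    if (any(lengths(cells) != 4)) {
      abort_restaple(sprintf("vstrand %d: %s cells must be 4-tuples", i, what),
                     "restaple_schema_error")
    }
    m <- matrix(as.integer(unlist(cells, use.names = FALSE)), ncol = 4, byrow = TRUE)
    if (anyNA(m) || any(m < -1)) {
      abort_restaple(sprintf("vstrand %d: %s pointers must be integers >= -1", i, what),
                     "restaple_schema_error")
    }
    m
  }
  scaf <- to_mat(v[["scaf"]], "scaf")
  stap <- to_mat(v[["stap"]], "stap")
  n <- nrow(scaf)
  if (nrow(stap) != n) {
    abort_restaple(sprintf("vstrand %d: scaf and stap lengths differ", i),
                   "restaple_schema_error")
  }
  grab_vec <- function(name, default) {
    x <- v[[name]]
    if (is.null(x)) return(rep.int(default, n))
    x <- as.integer(unlist(x, use.names = FALSE))
    if (length(x) != n) {
      abort_restaple(sprintf("vstrand %d: %s length mismatch", i, name),
                     "restaple_schema_error")
    }
    x
  }
  skip <- grab_vec("skip", 0L)
  loop <- grab_vec("loop", 0L)
  if (any(!skip %in% c(0L, -1L))) {
    abort_restaple(sprintf("vstrand %d: skip values must be 0 or -1", i),
                   "restaple_schema_error")
  }
  if (any(loop < 0L)) {
    abort_restaple(sprintf("vstrand %d: loop values must be >= 0", i),
                   "restaple_schema_error")
  }
  if (any(loop > 0L)) {
    abort_restaple(
      sprintf("vstrand %d carries loop (insertion) values > 0; insertions are not supported", i),
      "restaple_unsupported_error"
    )
  }
  sc <- v[["stap_colors"]]
  stap_colors <- if (is.null(sc) || length(sc) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    if (any(lengths(sc) != 2)) {
      abort_restaple(sprintf("vstrand %d: stap_colors entries must be pairs", i),
                     "restaple_schema_error")
    }
    matrix(as.integer(unlist(sc, use.names = FALSE)), ncol = 2, byrow = TRUE)
  }
  list(
    num = as.integer(v[["num"]]),
    row = if (is.null(v[["row"]])) 0L else as.integer(v[["row"]]),
    col = if (is.null(v[["col"]])) 0L else as.integer(v[["col"]]),
    scaf = scaf, stap = stap, skip = skip, loop = loop,
    stap_colors = stap_colors
  )
}

# caDNAno v2 files do not store the lattice; per-helix array lengths are
# multiples of 32 on the square lattice and 21 on the honeycomb lattice.
#' @keywords internal
#' @noRd
infer_lattice <- function(arr_len) {
  if (arr_len %% 32 == 0) "square" else if (arr_len %% 21 == 0) "honeycomb" else "square"
}

# Full pointer-symmetry validation. Violations name (helix num, idx, strand).
#' @keywords internal
#' @noRd
check_linkage <- function(design) {
  nums <- vapply(design$helices, function(h) h$num, integer(1))
  idx_of <- stats::setNames(seq_along(nums), nums)
  n <- nrow(design$helices[[1]]$scaf)
  for (kind in c("scaf", "stap")) {
    mats <- lapply(design$helices, `[[`, kind)
    for (hi in seq_along(mats)) {
      m <- mats[[hi]]
      for (side in c(1L, 3L)) { # columns (1,2) = 5' neighbour, (3,4) = 3' neighbour
        ph <- m[, side]
        pi <- m[, side + 1L]
        half <- xor(ph == CADNANO_SENTINEL, pi == CADNANO_SENTINEL)
        if (any(half)) {
          bad <- which(half)[1] - 1L
          abort_restaple(
            sprintf("half-sentinel pointer at helix %d idx %d (%s)", nums[hi], bad, kind),
            "restaple_linkage_error"
          )
        }
        live <- which(ph != CADNANO_SENTINEL)
        for (j in live) {
          th <- ph[j]; ti <- pi[j]
          thi <- idx_of[as.character(th)]
          if (is.na(thi) || ti < 0L || ti >= n) {
            abort_restaple(
              sprintf("dangling pointer at helix %d idx %d (%s): targets helix %d idx %d",
                      nums[hi], j - 1L, kind, th, ti),
            "restaple_linkage_error"
            )
          }
          back <- if (side == 1L) mats[[thi]][ti + 1L, c(3L, 4L)] else mats[[thi]][ti + 1L, c(1L, 2L)]
          if (back[1] != nums[hi] || back[2] != j - 1L) {
            abort_restaple(
              sprintf("asymmetric pointer pair at helix %d idx %d (%s)",
                      nums[hi], j - 1L, kind),
              "restaple_linkage_error"
            )
          }
        }
      }
    }
  }
  invisible(design)
}

#' Serialise a design to caDNAno version-2 JSON
#'
#' Emits JSON that caDNAno itself re-reads, with a stable field order across
#' runs so that identical designs produce byte-identical files. The design is
#' re-validated first; an inconsistent design raises a linkage error and no
#' output is produced.
#'
#' @param design A `cadnano_design` object.
#' @param file Optional path; when given the JSON is also written there.
#' @return The JSON text, invisibly when `file` is given.
#' @export
write_cadnano <- function(design, file = NULL) {
  stopifnot(inherits(design, "cadnano_design"))
  check_linkage(design)
  txt <- format_cadnano(design)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Deterministic hand-assembled serialiser (jsonlite does not guarantee a
# stable layout for caDNAno's mixed nested arrays). No validation here; the
# degenerate-case generator uses it to emit deliberately broken files.
#' @keywords internal
#' @noRd
format_cadnano <- function(design) {
  fmt_cells <- function(m) {
    paste0("[", m[, 1], ",", m[, 2], ",", m[, 3], ",", m[, 4], "]", collapse = ",")
  }
  fmt_colors <- function(m) {
    if (nrow(m) == 0) return("")
    paste0("[", m[, 1], ",", m[, 2], "]", collapse = ",")
  }
  hs <- vapply(design$helices, function(h) {
    paste0(
      '{"row":', h$row,
      ',"col":', h$col,
      ',"num":', h$num,
      ',"scaf":[', fmt_cells(h$scaf),
      '],"stap":[', fmt_cells(h$stap),
      '],"loop":[', paste(h$loop, collapse = ","),
      '],"skip":[', paste(h$skip, collapse = ","),
      '],"scafLoop":[],"stapLoop":[],"stap_colors":[', fmt_colors(h$stap_colors),
      "]}"
    )
  }, character(1))
  paste0('{"name":', jsonlite::toJSON(design$name, auto_unbox = TRUE),
         ',"vstrands":[', paste(hs, collapse = ","), "]}")
}

#' @export
print.cadnano_design <- function(x, ...) {
  n <- nrow(x$helices[[1]]$scaf)
  used_scaf <- sum(vapply(x$helices, function(h) sum(rowSums(h$scaf != CADNANO_SENTINEL) > 0), integer(1)))
  used_stap <- sum(vapply(x$helices, function(h) sum(rowSums(h$stap != CADNANO_SENTINEL) > 0), integer(1)))
  cat(sprintf(
    "caDNAno design \"%s\": %d helices (%s lattice), array length %d\n  scaffold-occupied cells: %d, staple-occupied cells: %d\n",
    x$name, length(x$helices), x$lattice, n, used_scaf, used_stap
  ))
  invisible(x)
}
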
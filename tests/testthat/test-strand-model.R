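# Strand tracing, crossover signatures and design metrics.

duplex <- make_helix_bundle(2, 64, "square", 16)

test_that("the duplex scaffold traces helix 0 then helix 1, 5' to 3'", {
  p <- trace_scaffold(duplex)
  expect_equal(nrow(p$positions), 64)
  expect_false(p$circular)
  expect_equal(p$positions[1, ], c(0L, 0L))
  # parity convention: scaffold increases along even helix 0
  expect_equal(p$positions[1:32, 2], 0:31)
  expect_equal(unique(p$positions[1:32, 1]), 0L)
  expect_equal(unique(p$positions[33:64, 1]), 1L)
  expect_equal(p$positions[33:64, 2], 31:0)
})

test_that("a circularised duplex traces as one circular path of 64", {
  d <- duplex
  # join scaffold 3' end (1, 0) back to 5' end (0, 0)
  d$helices[[2]]$scaf[1, c(3, 4)] <- c(0L, 0L)
  d$helices[[1]]$scaf[1, c(1, 2)] <- c(1L, 0L)
  p <- trace_scaffold(d)
  expect_true(p$circular)
  expect_equal(nrow(p$positions), 64)
  expect_equal(p$positions[1, ], c(0L, 0L)) # starts at lowest (helix, idx)
})

test_that("zero or multiple scaffold components raise a topology error", {
  cases <- make_degenerate_cases()
  d <- parse_cadnano(cases$two_scaffolds)
  err <- expect_error(trace_scaffold(d), class = "restaple_topology_error")
  expect_equal(err$count, 2)
})

test_that("staple tracing covers every staple cell exactly once", {
  for (d in list(duplex, make_helix_bundle(6, 1082, "honeycomb", 7))) {
    paths <- trace_staples(d)
    cells <- do.call(rbind, lapply(paths, `[[`, "positions"))
    occupied <- sum(vapply(d$helices, function(h) sum(rowSums(h$stap != -1L) > 0), integer(1)))
    expect_equal(nrow(cells), occupied)
    expect_equal(anyDuplicated(cells[, 1] * 1e6 + cells[, 2]), 0L)
  }
})

test_that("a design with no staple routing yields an empty staple list", {
  d <- duplex
  d$helices[[1]]$stap[] <- -1L
  d$helices[[2]]$stap[] <- -1L
  d$helices[[1]]$stap_colors <- matrix(integer(0), ncol = 2)
  expect_length(trace_staples(d), 0)
})

test_that("crossover offsets are the 0-based positions after each helix change", {
  # 32-nt staple crossing once between bases 15 and 16 (0-based)
  small <- make_helix_bundle(2, 32, "square", 8)
  st <- trace_staples(small)[[1]]
  expect_equal(nrow(st$positions), 32)
  expect_equal(crossover_offsets(st), 16L)
  # a staple confined to one helix has an empty signature
  one <- fake_path(20)
  expect_equal(crossover_offsets(one), integer(0))
  # equal signature lists compare equal as arrangements
  expect_identical(crossover_offsets(st), crossover_offsets(st))
})

test_that("duplex metrics: one scaffold and one staple crossover, density 31.25", {
  m <- design_metrics(duplex)
  expect_equal(m$scaffold_length, 64)
  expect_equal(m$scaffold_xovers, 1)
  expect_equal(m$staple_xovers, 1)
  expect_equal(m$xover_density, 1000 * 2 / 64)
})

test_that("a crossover-free single-helix duplex has density zero", {
  d <- duplex
  # strip helix 1 and cut the bend, leaving helix 0's 32-nt duplex
  d$helices[[1]]$scaf[32, c(3, 4)] <- c(-1L, -1L) # scaffold stops at (0, 31)
  d$helices[[1]]$stap[1, c(3, 4)] <- c(-1L, -1L)  # staple stops at (0, 0)
  d$helices[[2]]$scaf[] <- -1L
  d$helices[[2]]$stap[] <- -1L
  m <- design_metrics(d)
  expect_equal(m$scaffold_xovers + m$staple_xovers, 0)
  expect_equal(m$xover_density, 0)
})

test_that("crossover counts match a brute-force recount on the 24-helix fixture", {
  b <- make_helix_bundle(24, 6000, "honeycomb", 7)
  m <- design_metrics(b)
  expect_equal(m$scaffold_xovers, oracle_count_crossovers(list(trace_scaffold(b))))
  expect_equal(m$staple_xovers, oracle_count_crossovers(trace_staples(b)))
})

test_that("breaking a staple path off-crossover preserves the crossover count", {
  d <- make_helix_bundle(2, 64, "square", 16)
  before <- design_metrics(d)$staple_xovers
  d$helices[[1]]$stap[11, c(3, 4)] <- c(-1L, -1L) # break within helix 0
  d$helices[[1]]$stap[10, c(1, 2)] <- c(-1L, -1L)
  expect_equal(design_metrics(d)$staple_xovers, before)
  # breaking exactly on the crossover adjacency removes it
  d2 <- make_helix_bundle(2, 64, "square", 16)
  d2$helices[[1]]$stap[1, c(3, 4)] <- c(-1L, -1L) # (0,0) -> (1,0) severed
  d2$helices[[2]]$stap[1, c(1, 2)] <- c(-1L, -1L)
  expect_equal(design_metrics(d2)$staple_xovers, before - 1)
  expect_equal(design_metrics(d2)$scaffold_xovers, 1)
})

test_that("multiplicity statistics come from the layout grouping", {
  b <- make_helix_bundle(24, 6000, "honeycomb", 7)
  cfg <- design_config(k_unique = 10, iterations = 1, preset = "bundle", seed = 7)
  res <- run_search(b, cfg)
  cd <- res$candidates[[1]]
  m <- cd$metrics
  expect_equal(m$multiplicity_mean, m$staple_count / m$unique_count)
  expect_equal(m$unique_count, 10)
  sizes <- tabulate(cd$layout$group_of, nbins = 10)
  expect_equal(m$multiplicity_sd, sd(sizes))
})

test_that("skips shorten paths and scaffold length consistently", {
  d <- make_helix_bundle(2, 64, "square", 16)
  d$helices[[1]]$skip[c(3, 20)] <- -1L
  m <- design_metrics(d)
  expect_equal(m$scaffold_length, 62)
  paths <- trace_staples(d)
  expect_equal(sum(vapply(paths, function(p) nrow(p$positions), integer(1))), 62)
})
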
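# Segmentation of unbroken paths into staples and grouping into k classes.

test_that("config validation enforces the documented invariants", {
  expect_error(design_config(k_unique = 0), class = "restaple_argument_error")
  expect_error(design_config(k_unique = 5, len_min = 80, len_max = 70),
               class = "restaple_argument_error")
  expect_error(design_config(k_unique = 5, window = 1),
               class = "restaple_argument_error")
  expect_error(design_config(k_unique = 5, iterations = 2, n_best = 3),
               class = "restaple_argument_error")
  cfg <- design_config(k_unique = 10, preset = "short")
  expect_equal(c(cfg$len_min, cfg$len_max), c(25L, 62L))
  cfg <- design_config(k_unique = 10, preset = "long")
  expect_equal(c(cfg$len_min, cfg$len_max), c(60L, 125L))
  cfg <- design_config(k_unique = 10, preset = "bundle")
  expect_equal(c(cfg$len_min, cfg$len_max), c(38L, 77L))
})

test_that("a 120-nt path with a forced single-length palette cuts into two staples", {
  cfg <- design_config(k_unique = 1, len_min = 60, len_max = 60)
  set.seed(1)
  st <- segment_paths(list(fake_path(120)), cfg)
  expect_length(st, 2)
  expect_equal(vapply(st, `[[`, integer(1), "length"), c(60L, 60L))
})

test_that("a 130-nt path cuts into an exact two-part palette partition", {
  # enumerating palette partitions of 130 with two lengths in [60, 70]:
  # every solution is a pair (l1, l2), l1 + l2 = 130
  cfg <- design_config(k_unique = 2, len_min = 60, len_max = 70)
  for (s in 1:5) {
    set.seed(s)
    st <- segment_paths(list(fake_path(130)), cfg)
    lens <- vapply(st, `[[`, integer(1), "length")
    expect_length(lens, 2)
    expect_equal(sum(lens), 130)
    expect_true(all(lens >= 60 & lens <= 70))
  }
})

test_that("an unpartitionable path is a layout-infeasible error naming the path", {
  cfg <- design_config(k_unique = 2, len_min = 38, len_max = 77)
  err <- expect_error(segment_paths(list(fake_path(30)), cfg),
                      class = "restaple_infeasible_error")
  expect_match(conditionMessage(err), "shorter than len_min")
  # feasible bounds but impossible total after the retry budget
  cfg2 <- design_config(k_unique = 1, len_min = 60, len_max = 60)
  expect_error(segment_paths(list(fake_path(130)), cfg2, budget = 10),
               class = "restaple_infeasible_error")
})

test_that("partition exactness: staples tile each unbroken path in order", {
  b <- make_helix_bundle(24, 6000, "honeycomb", 7)
  paths <- trace_staples(b)
  cfg <- design_config(k_unique = 10, preset = "bundle")
  set.seed(3)
  st <- segment_paths(paths, cfg)
  layout <- assign_groups(st, cfg, paths = paths)
  expect_length(validate_layout(layout, cfg), 0)
  # concatenating each path's staples reproduces the path position-by-position
  for (pi in seq_along(paths)) {
    mine <- layout$staples[vapply(layout$staples, `[[`, integer(1), "source_path") == pi]
    mine <- mine[order(vapply(mine, `[[`, integer(1), "offset"))]
    rebuilt <- do.call(rbind, lapply(mine, function(s) s$path$positions))
    expect_equal(rebuilt, paths[[pi]]$positions)
  }
})

test_that("100 equal-length staples in 10 groups give 10 groups of 10", {
  cfg <- design_config(k_unique = 10, len_min = 60, len_max = 60)
  st <- replicate(100, fake_staple(60), simplify = FALSE)
  set.seed(1)
  layout <- assign_groups(st, cfg)
  sizes <- tabulate(layout$group_of, nbins = 10)
  expect_equal(sizes, rep(10L, 10))
})

test_that("two length classes with k = 2 split into one group per length", {
  cfg <- design_config(k_unique = 2, len_min = 60, len_max = 70)
  st <- c(replicate(50, fake_staple(60), simplify = FALSE),
          replicate(50, fake_staple(70), simplify = FALSE))
  set.seed(1)
  layout <- assign_groups(st, cfg)
  sizes <- tabulate(layout$group_of, nbins = 2)
  expect_equal(sort(sizes), c(50L, 50L))
  lens <- vapply(st, `[[`, integer(1), "length")
  for (g in 1:2) expect_length(unique(lens[layout$group_of == g]), 1)
})

test_that("fewer staples than groups is infeasible", {
  cfg <- design_config(k_unique = 10, len_min = 60, len_max = 60)
  st <- replicate(5, fake_staple(60), simplify = FALSE)
  expect_error(assign_groups(st, cfg), class = "restaple_infeasible_error")
})

test_that("validate_layout reports mixed-length groups and bounds violations", {
  cfg <- design_config(k_unique = 1, len_min = 38, len_max = 77)
  st <- list(fake_staple(60), fake_staple(61))
  layout <- structure(list(staples = st, group_of = c(1L, 1L), k = 1L, paths = NULL),
                      class = "staple_layout")
  v <- validate_layout(layout, cfg)
  expect_length(grep("mixes staple lengths", v), 1)
  layout2 <- structure(list(staples = list(fake_staple(30)), group_of = 1L,
                            k = 1L, paths = NULL), class = "staple_layout")
  v2 <- validate_layout(layout2, design_config(k_unique = 1, preset = "bundle"))
  expect_length(grep("outside \\[38, 77\\]", v2), 1)
})

test_that("identical (design, config, seed) reproduce the identical layout", {
  b <- make_helix_bundle(6, 1082, "honeycomb", 7)
  paths <- trace_staples(b)
  cfg <- design_config(k_unique = 5, preset = "bundle")
  set.seed(99); l1 <- assign_groups(segment_paths(paths, cfg), cfg)
  set.seed(99); l2 <- assign_groups(segment_paths(paths, cfg), cfg)
  expect_equal(l1, l2)
})

test_that("random breaks diversify crossover arrangements; the repetitive mode aligns them", {
  b <- make_helix_bundle(24, 6000, "honeycomb", 7)
  paths <- trace_staples(b)

  same_sig_fraction <- function(layout) {
    pairs <- 0L; same <- 0L
    for (g in seq_len(layout$k)) {
      members <- which(layout$group_of == g)
      if (length(members) < 2) next
      sigs <- lapply(layout$staples[members], `[[`, "signature")
      for (i in seq_along(sigs)) for (j in seq_len(i - 1L)) {
        pairs <- pairs + 1L
        if (identical(sigs[[i]], sigs[[j]])) same <- same + 1L
      }
    }
    same / pairs
  }

  cfg <- design_config(k_unique = 10, preset = "bundle", seed = 5)
  set.seed(5)
  lay <- assign_groups(segment_paths(paths, cfg), cfg, paths = paths)
  expect_lt(same_sig_fraction(lay), 1)

  cfg_rep <- design_config(k_unique = 10, preset = "bundle", seed = 5,
                           repetitive_arrangement = TRUE)
  set.seed(5)
  st_rep <- segment_paths(paths, cfg_rep)
  # equal-length unbroken paths share one cut pattern
  offs <- split(vapply(st_rep, `[[`, integer(1), "offset"),
                vapply(st_rep, `[[`, integer(1), "source_path"))
  expect_length(unique(offs), 1)
  set.seed(5)
  lay_rep <- assign_groups(st_rep, cfg_rep, paths = paths)
  expect_gte(same_sig_fraction(lay_rep), same_sig_fraction(lay))
})
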
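# Sequence assignment, scaffold derivation, motif counting, adapters.

test_that("random sequences are seed-deterministic and honour GC bounds", {
  set.seed(11); a <- random_sequence(12)
  set.seed(11); b <- random_sequence(12)
  expect_identical(a, b)
  expect_equal(nchar(a), 12)
  cfg <- design_config(k_unique = 1, gc_min = 0.4, gc_max = 0.6)
  set.seed(2)
  for (i in 1:20) {
    s <- random_sequence(10, cfg)
    expect_true(gc_fraction(s) >= 0.4 && gc_fraction(s) <= 0.6)
  }
  expect_error(random_sequence(0), class = "restaple_argument_error")
  tight <- design_config(k_unique = 1, gc_min = 0.999, gc_max = 1)
  expect_error(random_sequence(3, tight, retries = 5),
               class = "restaple_generation_error")
})

make_two_group_layout <- function() {
  st <- c(replicate(3, fake_staple(40), simplify = FALSE),
          replicate(3, fake_staple(50), simplify = FALSE))
  structure(list(staples = st, group_of = c(1L, 1L, 1L, 2L, 2L, 2L),
                 k = 2L, paths = NULL), class = "staple_layout")
}

test_that("predefined sequences are used verbatim, matched to groups by length", {
  layout <- make_two_group_layout()
  pre <- c(paste(rep("A", 50), collapse = ""), paste(rep("G", 40), collapse = ""))
  cfg <- design_config(k_unique = 2, sequences = pre)
  seqs <- assign_sequences(layout, cfg)
  expect_equal(seqs$provenance, "predefined")
  expect_setequal(seqs$sequences, pre)
  expect_equal(nchar(seqs$sequences), c(40L, 50L))

  bad <- design_config(k_unique = 2, sequences = c(pre[1], "ACGT"))
  err <- expect_error(assign_sequences(layout, bad),
                      class = "restaple_assignment_error")
  expect_match(conditionMessage(err), "length 40")
  expect_error(assign_sequences(layout, design_config(k_unique = 2, sequences = pre[1])),
               class = "restaple_assignment_error")
})

test_that("random mode yields exactly k distinct sequences of the group lengths", {
  layout <- make_two_group_layout()
  cfg <- design_config(k_unique = 2)
  set.seed(4)
  seqs <- assign_sequences(layout, cfg)
  expect_equal(seqs$provenance, "random")
  expect_equal(nchar(seqs$sequences), c(40L, 50L))
  expect_equal(length(unique(seqs$sequences)), 2)
})

test_that("the derived duplex scaffold is the staple's reverse complement along its path", {
  d <- make_helix_bundle(2, 64, "square", 16)
  scaf_path <- trace_scaffold(d)
  paths <- trace_staples(d)
  staple <- list(structure(list(path = paths[[1]], length = 64L,
                                signature = crossover_offsets(paths[[1]]),
                                source_path = 1L, offset = 1L), class = "staple"))
  layout <- structure(list(staples = staple, group_of = 1L, k = 1L, paths = paths),
                      class = "staple_layout")
  set.seed(8)
  sq <- paste(sample(c("A", "C", "G", "T"), 64, replace = TRUE), collapse = "")
  seqs <- structure(list(sequences = sq, provenance = "predefined"),
                    class = "sequence_set")
  scaffold <- derive_scaffold(scaf_path, layout, seqs)
  expect_equal(scaffold$length, 64)
  expect_length(scaffold$unpaired_positions, 0)

  # independent per-cell re-hybridisation
  candidate <- list(scaffold_path = scaf_path, scaffold = scaffold,
                    layout = layout, sequences = seqs)
  chk <- oracle_rehybridize(candidate)
  expect_equal(chk$fraction, 1)

  # single Watson-Crick spot check: staple base at cell (0, 31) is sq[1],
  # scaffold position 32 occupies the same cell
  sb <- substr(sq, 1, 1)
  expect_equal(substr(scaffold$bases, 32, 32),
               chartr("ACGT", "TGCA", sb))
})

test_that("uncovered scaffold cells are filled from the seeded stream and recorded", {
  d <- make_helix_bundle(2, 64, "square", 16)
  scaf_path <- trace_scaffold(d)
  full <- trace_staples(d)[[1]]
  # keep only the first 60 staple bases; 4 scaffold cells lose coverage
  part <- structure(list(kind = "staple",
                         positions = full$positions[1:60, ],
                         circular = FALSE), class = "strand_path")
  staple <- list(structure(list(path = part, length = 60L, signature = crossover_offsets(part),
                                source_path = 1L, offset = 1L), class = "staple"))
  layout <- structure(list(staples = staple, group_of = 1L, k = 1L, paths = NULL),
                      class = "staple_layout")
  seqs <- structure(list(sequences = paste(rep("A", 60), collapse = ""),
                         provenance = "predefined"), class = "sequence_set")
  set.seed(21); s1 <- derive_scaffold(scaf_path, layout, seqs)
  set.seed(21); s2 <- derive_scaffold(scaf_path, layout, seqs)
  expect_length(s1$unpaired_positions, 4)
  expect_identical(s1$bases, s2$bases)
})

test_that("motif counting is overlapping and strand-explicit", {
  expect_equal(count_motif("GGATGGGATG", "GGATG"), 2)
  expect_equal(count_motif("AAAAAA", "AAAA"), 3)
  expect_equal(count_motif("", "GGATG"), 0)
  expect_equal(count_motif("GGATG", "CATCC"), 0) # other strand needs the RC motif
  expect_error(count_motif("ACGT", ""), class = "restaple_argument_error")
})

test_that("adapter flanking concatenates, validates and screens", {
  sc <- structure(list(bases = paste(rep("ACGT", 16), collapse = ""),
                       length = 64L, unpaired_positions = integer(0)),
                  class = "scaffold_sequence")
  left <- paste(rep("A", 30), collapse = ""); right <- paste(rep("T", 30), collapse = "")
  out <- flank_with_adapters(sc, left, right)
  expect_equal(nchar(out), 64 + 60)
  expect_equal(attr(out, "forbidden_hits"), 0L)
  out2 <- flank_with_adapters(sc, "", "")
  expect_equal(unclass(out2)[1], sc$bases)
  expect_error(flank_with_adapters(sc, "ACGN", ""), class = "restaple_input_error")
  withhit <- structure(list(bases = "AAAGGATGAAA", length = 11L,
                            unpaired_positions = integer(0)),
                       class = "scaffold_sequence")
  expect_warning(res <- flank_with_adapters(withhit, "", ""), "forbidden-motif")
  expect_gte(attr(res, "forbidden_hits"), 1L)
})
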
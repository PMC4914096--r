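---
title: "Designing custom DNA-origami scaffolds from reusable staple sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing custom DNA-origami scaffolds from reusable staple sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restaple)
```

## The design problem

A scaffolded DNA origami folds one long single-stranded "scaffold" into a
target shape by hybridising it with many short "staple" oligonucleotides.
Conventionally every staple is a unique sequence, so a structure of a few
thousand nucleotides needs on the order of 150 separate syntheses. The
approach implemented here inverts the usual design direction: instead of
deriving staples from a fixed scaffold (such as M13mp18), it fixes a small
set of `k` reusable staple sequences, lays them out over the shape's staple
routing, and *derives* the scaffold as the forced Watson-Crick complement of
that layout. One unique staple sequence then binds the template at many
locations (about 10 locations each when `k = 10` on a ~6-kb, 24-helix
bundle), cutting the number of distinct strands by an order of magnitude.

The price is sequence repetitiveness. A scaffold templated by few reused
staples necessarily repeats itself, and highly repetitive DNA is hard to
synthesise, clone and amplify, and correlates with poorer folding yields.
The package therefore treats scaffold design as a randomised search: draw
many staple layouts, derive each candidate scaffold, score its
repetitiveness, and keep the least repetitive design.

## The repetitiveness score

A position of the scaffold is *repetitive* if it lies inside any window of
`w` bases (default `w = 12`) whose exact sequence occurs more than once in
the scaffold, on the same strand. The score of a scaffold is the fraction of
its nucleotides that are repetitive:

```{r metric}
repeat_coverage(strrep("ACGTACGTACGT", 4), window = 12)
```

Implementation notes, all deliberate choices:

* **Same-strand, exact matches.** Reverse-complement occurrences are not
  counted by default (`include_revcomp = TRUE` enables them for
  exploration); repetitiveness as a synthesis/cloning difficulty proxy is a
  same-strand notion.
* **Linear sequence.** The restriction-released scaffold is linear, so no
  wraparound windows are formed.
* **Window hashing, oracle-pinned.** Scoring hashes all length-`w`
  substrings (O(Lw)); its output is pinned in the test suite, window for
  window, to a brute-force O(L^2) all-pairs comparison oracle on hundreds of
  random sequences. The hash path is the implementation; the oracle defines
  correctness.
* **Case-folded input; non-ACGT characters are an error** naming the
  offending offset, rather than being silently dropped.

On the standard M13mp18 scaffold (GenBank X02513) this measure gives about
2%; the file is not redistributed, but `score_fasta()` reproduces the
baseline from a user-fetched copy (see `inst/extdata/README.md`).

## From caDNAno routing to a candidate scaffold

The pipeline consumes caDNAno version-2 JSON with *unbroken* staple routing
(staple paths drawn without breaks) and proceeds in four steps per candidate
draw:

1. **Segmentation** (`segment_paths()`). A palette of at most `k_unique`
   distinct staple lengths is drawn uniformly from `[len_min, len_max]`, and
   each unbroken path is cut into consecutive staples with lengths from the
   palette, partitioning the path exactly. The cutter walks a
   reachability DP so every prefix stays completable, and greedily prefers
   the least-used palette length (random tie-break) so lengths are consumed
   evenly — this is what keeps group sizes near the balanced value.
   Palettes that cannot tile every path are redrawn (budget 100).
2. **Grouping** (`assign_groups()`). Staples are partitioned into exactly
   `k_unique` non-empty, length-homogeneous groups. Groups per length are
   allocated by a minimax rule (repeatedly granting a group to the length
   with the largest per-group load); membership among equal-length staples
   is randomised. A whole layout is rejected and redrawn if any group size
   deviates from `staple_count / k_unique` by more than `multiplicity_tol`
   (default 2); hard enforcement would make small designs infeasible.
3. **Sequence assignment** (`assign_sequences()`). One i.i.d.-uniform random
   sequence per group (optional GC bounds, off by default; collisions
   redrawn so a candidate always carries exactly `k_unique` distinct
   sequences), or user-supplied sequences matched to groups by length and
   used verbatim.
4. **Scaffold derivation** (`derive_scaffold()`). Walking the scaffold path
   5'→3', every position takes the Watson-Crick complement of the staple
   base occupying the same (helix, index) cell; staples run antiparallel, so
   a staple read 3'→5' pairs with the scaffold read 5'→3'. Cells without
   staple coverage are filled from the seeded stream and recorded; they are
   included in repetitiveness scoring.

`run_search()` repeats this `iterations` times (default 100) and ranks
candidates by ascending coverage, ties broken by draw index. Each draw uses
an RNG sub-stream derived from `(seed, draw index)`, so draws are
independent of evaluation order, identical `(design, config, seed)` triples
give byte-identical exports, and infeasible draws are logged and skipped
rather than aborting the search.

Conventions that the rest of the package relies on:

* **Helix parity** (caDNAno): on even-numbered helices the scaffold runs
  5'→3' in increasing base index and staples in decreasing index; odd
  helices the reverse.
* **Crossover counting**: one count per helix-change adjacency per strand
  path, so a double crossover counts twice (once per strand). Densities are
  reported per 1,000 scaffold nucleotides. Published crossover densities do
  not always state their convention; ours is declared and used
  consistently.
* **Skips and loops**: `skip = -1` cells are omitted from paths and from
  the scaffold length; `loop` (insertion) values > 0 are rejected as
  unsupported rather than guessed at, since they complicate sequence
  indexing and the motivating designs do not use them.
* **BtsCI screening**: derived scaffolds are screened for `GGATG`/`CATCC`
  (the BtsCI recognition site used to release the scaffold from its cloning
  vector, and its reverse complement). Single-stranded internal sites are a
  minor concern in practice, so screening is advisory — a warning count,
  never a failure. Hairpin adapter sequences for cloning are user-supplied
  (`flank_with_adapters()`).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_unique` | — | sequences | number of reusable staple sequences |
| `iterations` | 100 | draws | candidate library size |
| `len_min`, `len_max` | 38, 77 | nt | staple length bounds; presets `short` = 25-62, `long` = 60-125, `bundle` = 38-77 |
| `window` | 12 | nt | minimum repeat length scored |
| `multiplicity_tol` | 2 | staples | allowed deviation of group sizes from `staple_count / k_unique` |
| `gc_min`, `gc_max` | off | fraction | optional GC filter for random sequences |
| `seed` | 1 | — | master seed for all randomness |
| `repetitive_arrangement` | FALSE | — | force one shared cut pattern across equal-length paths |

`repetitive_arrangement = TRUE` reproduces the known-bad condition in which
a reused staple crosses helices at identical intra-staple offsets at every
binding location; it exists so that the yield-depressing repetitive
arrangement can be studied, not as a recommended setting.

## The synthetic fixtures, and what they do and do not emulate

Real validation designs for this method are hand-routed caDNAno files that
are not redistributable, so the package generates its own
(`make_helix_bundle()`): `n` parallel helices with one scaffold strand and
unbroken staple serpentines, at three scales used throughout the tests — a
2-helix, 64-nt toy duplex; a 6-helix, ~1.1-kb bundle; and a 24-helix, ~6-kb
bundle. Routing is a uniform raster with crossovers at every permitted
position of the caDNAno honeycomb raster (`xover_spacing = 7`): staple
serpentines change helix every 7 nt and the scaffold boustrophedon every
21 nt, giving 181 crossovers per 1,000 scaffold nucleotides on the 24-helix
bundle — a deliberately high-crossover-density design. Fixture generation is
deterministic, and every fixture round-trips through the caDNAno writer and
parser unchanged.

What the fixture reproduces of the study conditions: the 24-helix, ~6-kb
scale; bundle staple lengths 38-77 nt; the binding multiplicities that
follow from them (about 10.8, 7.3 and 5.7 template locations per sequence
at `k` = 10, 15, 20 on the top-ranked candidates, matching the reported
10 ± 2, 7 ± 1, 5 ± 1); and the qualitative law that the best attainable
repetitiveness falls strictly as `k` grows.

What it does not reproduce: the *absolute* repetitiveness of hand-routed
designs. On this fixture the acceptance script measures best-of-20-library
coverage of about 49% at `k = 10` and about 18% at `k = 20` (seed 1),
against the roughly 56%-to-39% range that comparable hand-routed bundles
attain.
The gap has a geometric cause: with uniform 7-nt staple runs, a 12-nt
window never fits inside a single staple-helix domain, so repeats can only
arise from recurring multi-staple junction contexts, whose frequency falls
roughly with the square of `k` — steeper than observed on irregular
hand-routed geometries, where longer and more varied staple runs let
single-domain repeats dominate. Uniform rasters with longer runs overshoot
in the other direction (70-95% coverage). A fixture on a uniform raster can
therefore bracket, but not match, the absolute repetitiveness of an
irregular design; passing tests on these fixtures demonstrate the
correctness of the machinery (tracing, segmentation, complementarity,
scoring, ranking, reproducibility) and the direction and rough scale of the
`k` trade-off, not absolute coverage values for any particular real
geometry.

The synthetic duplex toy is likewise only a topology probe (one scaffold
crossover, one staple crossover, density 31.25 per 1,000 nt); it exercises
parser, tracer and writer edge cases, not design realism.

## Numerical and degenerate-input choices

* Retry budgets: 100 palette redraws per segmentation, 50 layout redraws per
  draw for multiplicity balance, 1,000 redraws for a GC-bounded sequence;
  exhausting any budget is a classed, catchable condition
  (`restaple_infeasible_error`, `restaple_generation_error`), and
  `run_search()` records such draws instead of failing.
* Ties everywhere are broken by the seeded stream, never by input order.
* Designs with zero or several scaffold components, dangling or asymmetric
  linkage pointers, mixed array lengths, or insertion loops are rejected
  with classed errors naming the offending cell; `make_degenerate_cases()`
  emits files triggering each failure mode.
* Sequences shorter than the window score exactly 0; empty staple routing
  traces to an empty list; circular strands are traced from their lowest
  (helix, index) position and carry a `circular` flag.
* Exports are cross-validated from the written files alone (re-parse,
  re-trace, re-hybridise every staple against the exported scaffold); on any
  mismatch the export is removed rather than left half-written.

## Known limitations

* caDNAno version-2 JSON only; scadnano and caDNAno 2.5 files are rejected
  with a clear message. Insertions (`loop > 0`) are unsupported.
* No thermodynamic or mechanical modelling: staple breaks are placed by the
  randomised palette cutter, not optimised for seam placement or melting
  behaviour.
* Repetitiveness is the only ranking criterion, as in the motivating
  workflow; GC content and restriction-site screening are advisory.
* Multi-scaffold designs and odd helix counts are outside the fixture
  generator's raster (the parser and search accept any valid single-scaffold
  design).
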
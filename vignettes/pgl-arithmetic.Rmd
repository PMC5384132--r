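---
title: "Paired-genomic-loci arithmetic: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-genomic-loci arithmetic: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgltools)
```

## The data model

Chromatin-interaction assays (Hi-C, ChIA-PET) measure physical contacts
between two genomic regions at once.  A called interaction — a "loop" — is
therefore a *pair* of intervals, not one: the two anchors, locus A and
locus B.  Single-locus containers (BED plus bedtools) cannot express
pair-aware questions such as "do these two loops connect the same two
regions?", and bedpe-style files allow the two anchors in either order,
which makes programmatic comparison awkward.

The PGL (paired-genomic-loci) format used here fixes both problems with
two structural rules:

1. **Entry-internal order.**  Within every entry, locus A precedes (or
   equals) locus B under the order *chromosome byte-lexicographically,
   then start, then end*.  Chromosome names compare as plain strings —
   `chr1 < chr10 < chr15 < chr22 < chr7 < chrX < chrY` — with no
   natural-number parsing, so the order is unambiguous for any naming
   scheme.
2. **File order.**  Entries sort on the six coordinate columns
   sequentially: chromA, startA, endA, chromB, startB, endB.

A file is six required tab-separated columns (chromA, startA, endA,
chromB, startB, endB), free annotation columns from column 7 on, and
`#`-prefixed header lines.  Coordinates are **0-based half-open**, the
BED convention; nothing else interoperates cleanly with BED inputs to
`pgl_intersect1d()` and friends, and the bedpe lineage of paired formats
uses the same convention.  Annotation text is treated as opaque bytes:
the package stores columns 7+ as a single tab-joined string per entry and
never re-formats it, which is what makes `read_pgl()`/`write_pgl()`
round-trip byte-exactly and lets every operation guarantee annotation
preservation for pass-through entries.

Degenerate inputs: zero-length loci (`start == end`) are accepted on
parse but overlap nothing (permissive read, strict semantics);
negative-length loci are a parse error.  Coordinates must match
`^[0-9]+$` — `1e3` would be silently rewritten by numeric parsing and
break byte round trips, so it is rejected.  Comment lines are accepted
anywhere in a file and are collected to the top on write.

## The sorted-sweep overlap engine

Two entries overlap only when **both** anchors overlap (half-open
interval logic per anchor, on the same chromosome).  This is the single
predicate behind intersect, coverage, subtract and the 1D operations.

For sorted single-locus files, overlapping records are consecutive: if
records 1 and 3 overlap, record 2 must overlap both, so a scan can stop
at the first miss.  For sorted PGL files that argument survives **only on
the A axis**.  Consecutive entries can share overlapping A anchors while
their B anchors land far apart, so overlapping entry *pairs* are not
consecutive.  The canonical four-entry pattern (A anchors of entries 1–4
all mutually overlapping; B anchors pairing 1 with 3 and 2 with 4) is the
worked example in the test suite: the engine must report exactly the
cross pairs (1,3) and (2,4) plus the self pairs.

`pgl_find_overlaps()` therefore sweeps on A and tests 2D overlap
explicitly:

* For each file-1 entry it scans file 2 from a maintained **recheck
  index**: the first file-2 position whose locus A could still overlap
  the current (or any later) file-1 locus A.  The index only advances
  past file-2 entries whose locus A ends at or before the current file-1
  locus A start (or sits on an earlier chromosome) — safe because file-1
  A starts are non-decreasing.
* The scan stops at the first file-2 entry whose locus A start passes
  the current file-1 locus A end.  Between the recheck index and the stop
  point every candidate is tested on both anchors; B-axis misses are
  skipped, never used to stop the scan.

Operations that rely on sortedness **fail loudly** on unsorted input
rather than auto-sorting (silent resorting hides pipeline bugs); objects
already verified sorted skip the check, which is the in-memory equivalent
of a trust-the-presorted flag.  Correctness is checked against an
intentionally naive all-pairs oracle (`brute_overlaps()`) that makes no
sorting assumptions at all, so the two routes cannot share a bug.

## Operation semantics and the open choices behind them

**Distance between entries** (`pgl_entry_distance()`, used by
`pgl_closest()` and `pgl_merge()`) is the *sum* of the per-anchor gaps,
infinite as soon as either anchor pair is cross-chromosomal.  A metric had
to be chosen; the sum penalises displacement at both anchors and reduces
to familiar 1D behaviour when one gap is zero.  A max-of-gaps metric
would be equally defensible; the sum is the package's committed choice.
Consequence: `distance = 100` in `pgl_merge()` admits any split of 100
bases across the two anchors.

**Merge** groups entries into connected components of the relation
"distance ≤ d" and, because merged bounding boxes grow, re-evaluates the
relation against the growing boxes until a fixpoint.  Whether a
single-pass or transitive closure is "the" semantics is not observable
from the format; the fixpoint closure was chosen because it makes the
operation idempotent and gives the clean postcondition that no two output
entries are within d of each other — both properties are asserted in the
test suite.  Summary statistics (`count`, `sum`, `min`, `max`, `mean`,
`collapse`, `distinct`) address annotation columns by their 1-based file
column number (≥ 7), matching the command line's `-c 7 -o count,mean`.

**Subtract** treats each entry as an axis-aligned rectangle in the
(A coordinate) × (B coordinate) plane and removes the union of all
2D-overlapping file-2 rectangles.  The remainder is decomposed by
guillotine cuts along A first: A-left and A-right strips keep the full B
interval, the A-overlap strip keeps the B remainders.  Any decomposition
covering the same base-pair cells would be acceptable — the tests compare
rasterized unit-cell sets, not rectangle lists — but the A-first cut is
deterministic and emits at most four fragments per removed rectangle.
Overlap at a single anchor leaves an entry untouched: the 2D region
removed must be covered in both dimensions.  When an entry's own two
anchors overlap each other, fragments can come out with the loci
reversed; they are re-normalized before the output is sorted.

**Intersect** has six modes mirroring bedtools idioms: intersection
rectangles (per-locus max-start/min-end, the default), report-file-1
(`-wa`), append-file-2 (`-wb`), unique (`-u`), no-overlap (`-v`), and
base-counts (`-bc`, the intersection rectangle plus the per-anchor
overlap widths).  The "union" of two files in this algebra is the
concatenation of report modes, not a geometric union, so no separate
union mode exists.

**Closest** (and `pgl_closest1d()`) report *all* tied candidates, one
line each, in file-2/BED input order — dropping ties silently would bias
downstream annotation counts.  With no finite-distance candidate the
entry is still emitted, with `.` placeholder columns and distance −1.

**Window** uses full containment (not mere overlap) of the selected
anchors, with `both`/`either`/`anchorA`/`anchorB` modes; `both` can never
keep an inter-chromosomal entry.

**Expand** pads both anchors symmetrically, floors starts at zero, and
re-sorts; padding preserves the A-before-B invariant but the result is
re-checked anyway.

Inter-chromosomal entries participate in every operation; the
overlap/distance rules make cross-chromosome terms false or infinite
naturally, so no special-casing exists anywhere.

## Converters

* **bedpe → PGL** (`format_bedpe()`): loci are swapped into A/B order per
  line, annotations preserved, output sorted.  Lines with a `.`
  chromosome (unknown mate, legal in the bedpe dialect) are skipped with
  a counted warning.
* **Triplet sparse matrix → PGL** (`format_trip_sparse()`): fixed to the
  HiC-Pro dialect — a bin table `chrom start end index` plus `i j count`
  triplets.  Each triplet becomes one entry from its two bins with the
  count as annotation; unknown or duplicate bin indices are hard errors.
  Count mass is conserved (tested).
* **SAM → PGL** (`sam_to_pgl()`): text SAM; records are grouped by QNAME
  rather than trusting TLEN/PNEXT, because PNEXT gives the mate start but
  not its end.  Each mate's reference span is `[POS−1, POS−1+len)` where
  `len` is the CIGAR reference-consumed length (M/D/N/=/X consume,
  I/S/H/P do not) — exact by construction.  Unmapped, secondary and
  supplementary records are dropped; a QNAME with more than two surviving
  records is an error, with exactly two it yields one entry annotated
  with the QNAME.

Exporters: UCSC browser output uses the classic two-block BED12
representation (blocks are the anchors, the record spans anchor A start
to anchor B end); entries whose anchors overlap cannot be legal BED12 and
are skipped with a warning rather than fudged, as are inter-chromosomal
entries.  Juicebox output is the 7-column 2D annotation text with an
`R,G,B` color column.  `pgl_to_interactions()` writes 10-column bedpe
(`name score strand1 strand2` appended), the most format-stable entry
point of bedpe-consuming interaction packages.  `pgl_condense()` emits
the two discrete anchors per entry; `pgl_find_loops()` emits the loop
interior (anchor A start to anchor B end) for intra-chromosomal entries
and one record per anchor for inter-chromosomal ones.

## The command line

Every operation is a subcommand of the `pgltools` executable installed
under the package's `exec/` directory.  `-` denotes standard input (one
slot at most), results stream to standard out and all diagnostics to
standard error, so commands compose:

```sh
pgltools sort a.pgl | pgltools merge - -d 1000 -c 7 -o count,mean
```

Flag conventions follow bedtools where a familiar idiom exists (`-a`/`-b`
inputs, `-d` distance, `-c`/`-o` merge statistics, `-u`/`-v`/`-wa`/`-wb`
intersect modes).  Exit codes: 0 success, 1 data or sort-order error,
2 usage error.  The test suite asserts that a piped
`sort | merge | intersect` is byte-identical to the in-process function
composition.

## Synthetic fixtures and what passing tests mean

`pgl_fixture()` generates the structural shape of loop-call data: two
anchors of 10–1000 bp on named chromosomes (default two chromosomes of
100 kb), intra-chromosomal entries with an anchor gap drawn uniformly
from 1–50 kb, a 10% inter-chromosomal fraction, and uniform numeric
annotation columns — all reproducible bit-exactly from a seed without
disturbing the caller's RNG.  The rasterization oracles
(`pgl_rasterize()`, per-base 2D cells) require small coordinates, so
conservation tests use 1 kb chromosomes with 5–40 bp anchors; the
rasterizer refuses coordinates above its cap to prevent misuse.

The fixtures deliberately model no biology: no contact-frequency decay
with distance, no anchor clustering at CTCF sites, no coverage
inhomogeneity.  Passing tests therefore demonstrate the *combinatorial
and set-algebraic correctness* of the operations on structurally valid
data of realistic shape — they do not validate biological
interpretations drawn from real Hi-C data.  One structural simplification
matters for semantics: generated entries never have their two anchors
overlapping each other, so the fragment re-normalization path in the
subtract operations is exercised by construction only in unit tests, not
by the random fixtures.

Problem sizes in the checked properties — 100 fixture pairs of 100
entries for sweep-vs-oracle agreement, 40 pairs of 20 small-coordinate
entries for cell-set conservation, 200-entry files for the merge contract
at gap allowances 0, 100 and 10⁴ — were chosen so the whole suite
exercises every operation at full breadth in well under a minute of
desk-scale compute; all sorting is in-memory, sized for loop-call data
sets (10⁴–10⁶ entries), not for raw read-level data.

## Known limitations

* Text formats only: no BAM/CRAM, `.hic` or cooler ingest, and no
  transparent gzip.
* No strand semantics (PGL has no strand columns) and no
  chromosome-alias or assembly awareness; `chr1` and `1` are different
  chromosomes.
* `pgl_merge()` is quadratic within a (chromA, chromB) group per fixpoint
  round; fine at loop-call scale, not intended for contact-matrix-sized
  inputs.
* The distance metric and the merge closure are committed design choices
  (see above); pipelines comparing against other paired-loci tools should
  confirm matching conventions before comparing `closest`/`merge` output.
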
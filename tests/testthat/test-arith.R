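# 2D arithmetic: intersect, merge, subtract, window, coverage, closest, expand.

test_that("intersect emits per-locus interval intersections with base counts", {
  a <- pgl(entries_df(100, 200, 500, 600))
  b <- pgl(entries_df(150, 250, 550, 650))
  got <- as.data.frame(pgl_intersect(a, b))
  expect_equal(unlist(got[1, c("startA", "endA", "startB", "endB")],
                      use.names = FALSE), c(150L, 200L, 550L, 600L))
  bc <- as.data.frame(pgl_intersect(a, b, mode = "base-counts"))
  expect_equal(bc$annotations, "50\t50")
})

test_that("intersect mode family behaves on identical files", {
  f <- pgl_fixture(40, seed = 12)
  expect_identical(as.data.frame(pgl_intersect(f, f, mode = "unique")),
                   as.data.frame(f))
  expect_equal(pgl_length(pgl_intersect(f, f, mode = "no-overlap")), 0L)
  wa <- pgl_intersect(f, f, mode = "report-a")
  expect_gte(pgl_length(wa), pgl_length(f))
  # unique + no-overlap partition file 1
  g <- pgl_fixture(40, seed = 13)
  expect_equal(pgl_length(pgl_intersect(f, g, mode = "unique")) +
                 pgl_length(pgl_intersect(f, g, mode = "no-overlap")),
               pgl_length(f))
})

test_that("append-b mode carries the matching file-2 entry as annotations", {
  a <- pgl(entries_df(100, 200, 500, 600, ann = "loopA"))
  b <- pgl(entries_df(150, 250, 550, 650, ann = "loopB"))
  got <- as.data.frame(pgl_intersect(a, b, mode = "append-b"))
  expect_equal(got$annotations, "loopA\tchr1\t150\t250\tchr1\t550\t650\tloopB")
  expect_equal(got$startA, 100L)
})

test_that("intersect conserves rasterized cells", {
  for (s in 1:6) {
    f1 <- small_fixture(25, seed = s)
    f2 <- small_fixture(25, seed = s + 300)
    expect_identical(pgl_rasterize(pgl_intersect(f1, f2)),
                     sort(intersect(pgl_rasterize(f1), pgl_rasterize(f2))))
  }
})

test_that("merge takes bounding boxes over transitive overlap chains", {
  two <- pgl(entries_df(c(100, 150), c(200, 250), c(500, 550), c(600, 650)))
  m <- as.data.frame(pgl_merge(two))
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("startA", "endA", "startB", "endB")],
                      use.names = FALSE), c(100L, 250L, 500L, 650L))
  # chain: E1 overlaps E2, E2 overlaps E3, E1 does not overlap E3
  chain <- pgl(entries_df(c(100, 180, 260), c(200, 280, 360),
                          c(1000, 1080, 1160), c(1100, 1180, 1260)))
  expect_false(pgl_entry_overlap(chain$entries[1, ], chain$entries[3, ]))
  mc <- as.data.frame(pgl_merge(chain))
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$endA, 360L)
})

test_that("merge distance uses the summed per-anchor gap", {
  f <- pgl(entries_df(c(100, 250), c(200, 300), c(500, 650), c(600, 700)))
  expect_equal(pgl_length(pgl_merge(f, distance = 100)), 1L) # 50 + 50 <= 100
  expect_equal(pgl_length(pgl_merge(f, distance = 99)), 2L)
})

test_that("merge is idempotent and separates output by more than the distance", {
  for (d in c(0, 100, 10000)) {
    f <- pgl_fixture(80, seed = 31)
    m <- pgl_merge(f, distance = d)
    expect_identical(pgl_merge(m, distance = d)$entries[, 1:6],
                     m$entries[, 1:6])
    e <- as.data.frame(m)
    n <- nrow(e)
    if (n > 1) {
      i <- rep(seq_len(n), each = n); j <- rep(seq_len(n), times = n)
      keep <- i < j
      dd <- pgl_entry_distance(e[i[keep], ], e[j[keep], ])
      expect_true(all(dd > d))
    }
  }
})

test_that("merge summary statistics cover count, numeric and text reductions", {
  f <- pgl(entries_df(c(100, 150, 900), c(200, 250, 950),
                      c(500, 550, 5000), c(600, 650, 5050),
                      ann = c("2\tx", "4\ty", "6\tz")))
  m <- pgl_merge(f, stat_cols = c(7L, 7L, 7L, 8L, 7L),
                 stat_ops = c("count", "sum", "mean", "collapse", "max"))
  e <- as.data.frame(pgl_sort(m))
  merged <- e[e$startA == 100L, ]
  expect_equal(merged$annotations, "2\t6\t3\tx,y\t4")
  single <- e[e$startA == 900L, ]
  expect_equal(single$annotations, "1\t6\t6\tz\t6")
  expect_error(pgl_merge(f, stat_cols = 9L, stat_ops = "sum"),
               "no annotation column")
})

test_that("subtract decomposes the 2D remainder by guillotine cuts on A", {
  a <- pgl(entries_df(100, 300, 1000, 1300, ann = "orig"))
  b <- pgl(entries_df(150, 200, 1100, 1200))
  got <- as.data.frame(pgl_subtract(a, b))
  expect_equal(nrow(got), 4L)
  expect_true(all(got$annotations == "orig"))
  key <- sprintf("%d-%d x %d-%d", got$startA, got$endA, got$startB, got$endB)
  expect_setequal(key, c("100-150 x 1000-1300", "200-300 x 1000-1300",
                         "150-200 x 1000-1100", "150-200 x 1200-1300"))
})

test_that("subtract removes covered entries and ignores one-anchor overlap", {
  a <- pgl(entries_df(100, 300, 1000, 1300))
  cover <- pgl(entries_df(50, 400, 900, 1400))
  expect_equal(pgl_length(pgl_subtract(a, cover)), 0L)
  one_anchor <- pgl(entries_df(100, 300, 5000, 5100))
  expect_identical(as.data.frame(pgl_subtract(a, one_anchor))[, 1:6],
                   as.data.frame(a)[, 1:6])
})

test_that("subtract conserves cells and emits disjoint fragments per entry", {
  for (s in 1:6) {
    f1 <- small_fixture(25, seed = s + 600)
    f2 <- small_fixture(25, seed = s + 900)
    out <- pgl_subtract(f1, f2)
    expect_identical(pgl_rasterize(out),
                     sort(setdiff(pgl_rasterize(f1), pgl_rasterize(f2))))
    # fragments of any single entry never overlap each other
    for (i in seq_len(pgl_length(f1))) {
      frags <- pgl_subtract(pgl(f1$entries[i, , drop = FALSE],
                                sorted = "verified"), f2)
      fe <- as.data.frame(frags)
      n <- nrow(fe)
      if (n > 1) {
        ii <- rep(seq_len(n), each = n); jj <- rep(seq_len(n), times = n)
        keep <- ii < jj
        expect_false(any(pgl_entry_overlap(fe[ii[keep], ], fe[jj[keep], ])))
      }
    }
  }
})

test_that("window filters by containment with anchor modes", {
  f <- pgl(entries_df(c(100, 100), c(200, 200), c(500, 500), c(600, 600),
                      chromB = c("chr1", "chr2")))
  expect_equal(pgl_length(pgl_window(f, "chr1:0-5000", mode = "both")), 1L)
  # inter-chromosomal entries can never satisfy mode "both"
  expect_equal(as.data.frame(pgl_window(f, "chr1:0-5000"))$chromB, "chr1")
  expect_equal(pgl_length(pgl_window(f, "chr1:0-300", mode = "either")), 2L)
  expect_equal(pgl_length(pgl_window(f, "chr1:0-300", mode = "anchorB")), 0L)
  expect_equal(pgl_length(pgl_window(f, "chr2:0-1000", mode = "anchorB")), 1L)
  # both-mode output is a subset of either-mode output
  g <- pgl_fixture(60, seed = 8)
  both <- as.data.frame(pgl_window(g, "chr1:0-60000", mode = "both"))
  either <- as.data.frame(pgl_window(g, "chr1:0-60000", mode = "either"))
  expect_true(all(apply(both[, 1:6], 1, paste, collapse = "|") %in%
                    apply(either[, 1:6], 1, paste, collapse = "|")))
})

test_that("coverage counts overlapping file-2 entries with multiplicity", {
  loop <- pgl(entries_df(100, 200, 500, 600))
  reads <- pgl(entries_df(c(110, 120, 130), c(160, 170, 180),
                          c(510, 520, 530), c(560, 570, 580)))
  got <- as.data.frame(pgl_coverage(loop, reads))
  expect_equal(got$annotations, "3")
  none <- pgl(entries_df(5000, 5100, 9000, 9100))
  expect_equal(as.data.frame(pgl_coverage(none, reads))$annotations, "0")
  f <- pgl_fixture(30, seed = 40)
  self_counts <- as.integer(as.data.frame(pgl_coverage(f, f))$annotations |>
                              sapply(\(x) utils::tail(strsplit(x, "\t")[[1]], 1)))
  expect_true(all(self_counts >= 1L))
})

test_that("coverage matches brute-force counts on random fixtures", {
  for (s in 1:8) {
    f1 <- small_fixture(30, seed = s + 50)
    f2 <- small_fixture(30, seed = s + 70)
    got <- as.data.frame(pgl_coverage(f1, f2))
    counts <- as.integer(vapply(strsplit(got$annotations, "\t"),
                                function(p) p[length(p)], ""))
    br <- brute_overlaps(f1, f2)
    expected <- vapply(seq_len(pgl_length(f1)),
                       function(i) sum(br$idx1 == i), integer(1))
    expect_identical(counts, expected)
  }
})

test_that("closest picks the minimal summed gap, reports ties and placeholders", {
  a <- pgl(entries_df(100, 200, 500, 600))
  b <- pgl(entries_df(c(210, 250), c(220, 300), c(610, 700), c(630, 800),
                      ann = c("near", "far")))
  got <- as.data.frame(pgl_closest(a, b))
  expect_equal(nrow(got), 1L)
  parts <- strsplit(got$annotations, "\t")[[1]]
  expect_equal(parts[7], "near")
  expect_equal(parts[8], "20") # gaps 10 (A) + 10 (B)
  # overlapping candidate gives distance 0
  ov <- pgl(entries_df(150, 250, 550, 650))
  expect_match(as.data.frame(pgl_closest(a, ov))$annotations, "\t0$")
  # ties: both candidates emitted in file-2 order
  tie <- pgl(entries_df(c(210, 210), c(220, 220), c(610, 610), c(630, 630),
                        ann = c("t1", "t2")))
  gt <- as.data.frame(pgl_closest(a, tie))
  expect_equal(nrow(gt), 2L)
  expect_match(gt$annotations[1], "t1")
  expect_match(gt$annotations[2], "t2")
  # no finite candidate: placeholders and distance -1
  far <- pgl(entries_df(1, 2, 3, 4, chromA = "chr9"))
  expect_equal(as.data.frame(pgl_closest(a, far))$annotations,
               ".\t.\t.\t.\t.\t.\t-1")
})

test_that("expand pads both loci, floors at zero and re-sorts", {
  f <- pgl(entries_df(100, 200, 500, 600))
  e <- as.data.frame(pgl_expand(f, 50))
  expect_equal(unlist(e[1, c("startA", "endA", "startB", "endB")],
                      use.names = FALSE), c(50L, 250L, 450L, 650L))
  low <- pgl(entries_df(20, 100, 500, 600))
  expect_equal(as.data.frame(pgl_expand(low, 50))$startA, 0L)
  g <- pgl_fixture(30, seed = 44)
  expect_identical(as.data.frame(pgl_expand(g, 0)), as.data.frame(g))
  expect_error(pgl_expand(g, -1), "non-negative")
})
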
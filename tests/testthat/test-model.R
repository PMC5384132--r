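# Core ordering and overlap semantics.

test_that("chromosome order is byte-lexicographic on the full string", {
  expect_equal(chrom_compare("chr1", "chr10"), -1L)
  expect_equal(chrom_compare("chr10", "chr15"), -1L)
  expect_equal(chrom_compare("chr22", "chr7"), -1L)
  expect_equal(chrom_compare("chr7", "chrX"), -1L)
  expect_equal(chrom_compare("chrX", "chrX"), 0L)
  expect_equal(chrom_compare("chrY", "chrX"), 1L)
  # vectorised with recycling
  expect_equal(chrom_compare(c("chr1", "chr9"), "chr2"), c(-1L, 1L))
})

test_that("chrom_compare is a total order (antisymmetric, transitive)", {
  set.seed(42)
  pool <- c("chr1", "chr10", "chr2", "chr22", "chr7", "chrX", "chrY", "scaffold_1")
  for (rep in 1:200) {
    abc <- sample(pool, 3, replace = TRUE)
    ab <- chrom_compare(abc[1], abc[2])
    ba <- chrom_compare(abc[2], abc[1])
    expect_identical(ab, -ba)
    bc <- chrom_compare(abc[2], abc[3])
    ac <- chrom_compare(abc[1], abc[3])
    if (ab <= 0L && bc <= 0L) expect_lte(ac, 0L)
    if (ab >= 0L && bc >= 0L) expect_gte(ac, 0L)
  }
})

test_that("locus overlap is half-open, chromosome-aware and symmetric", {
  expect_true(locus_overlap("chr1", 100, 200, "chr1", 150, 250))
  expect_false(locus_overlap("chr1", 100, 200, "chr1", 200, 300)) # abutting
  expect_false(locus_overlap("chr1", 100, 200, "chr2", 100, 200))
  expect_false(locus_overlap("chr1", 150, 150, "chr1", 100, 200)) # zero-length
  set.seed(7)
  for (rep in 1:100) {
    s1 <- sample(0:50, 1); e1 <- s1 + sample(0:20, 1)
    s2 <- sample(0:50, 1); e2 <- s2 + sample(0:20, 1)
    expect_identical(locus_overlap("chr1", s1, e1, "chr1", s2, e2),
                     locus_overlap("chr1", s2, e2, "chr1", s1, e1))
  }
})

test_that("locus distance is the gap, zero on overlap, Inf across chromosomes", {
  expect_equal(locus_distance("chr1", 100, 200, "chr1", 250, 300), 50)
  expect_equal(locus_distance("chr1", 100, 200, "chr1", 150, 250), 0)
  expect_equal(locus_distance("chr1", 100, 200, "chr1", 200, 300), 0) # abutting
  expect_equal(locus_distance("chr1", 100, 200, "chr2", 250, 300), Inf)
})

test_that("entry overlap requires both anchors and entry distance sums gaps", {
  a <- entries_df(100, 200, 500, 600)
  expect_true(pgl_entry_overlap(a, entries_df(150, 250, 550, 650)))
  expect_false(pgl_entry_overlap(a, entries_df(150, 250, 700, 800)))
  expect_true(pgl_entry_overlap(a, a)) # reflexive for nonzero-length loci
  expect_equal(pgl_entry_distance(a, entries_df(250, 300, 700, 800)), 150)
  expect_equal(pgl_entry_distance(a, entries_df(150, 250, 550, 650)), 0)
  inter <- entries_df(100, 200, 500, 600, chromA = "chr1", chromB = "chr2")
  expect_equal(pgl_entry_distance(a, inter), Inf)
})

test_that("entry distance is zero exactly when entries overlap or abut", {
  set.seed(11)
  for (rep in 1:200) {
    mk <- function() entries_df(sA <- sample(0:80, 1), sA + sample(1:20, 1),
                                sB <- sample(100:180, 1), sB + sample(1:20, 1))
    a <- mk(); b <- mk()
    d <- pgl_entry_distance(a, b)
    if (pgl_entry_overlap(a, b)) expect_equal(d, 0)
    if (d > 0) expect_false(pgl_entry_overlap(a, b))
  }
})

test_that("normalization enforces A-before-B, is idempotent, keeps annotations", {
  e <- data.frame(chromA = "chr2", startA = 10L, endA = 20L,
                  chromB = "chr1", startB = 10L, endB = 20L,
                  annotations = "keep\tme", stringsAsFactors = FALSE)
  n1 <- pgl_normalize(e)
  expect_equal(n1$chromA, "chr1")
  expect_equal(n1$chromB, "chr2")
  expect_equal(n1$annotations, "keep\tme")
  expect_identical(pgl_normalize(n1), n1)
  e2 <- entries_df(500, 600, 100, 200)
  expect_equal(pgl_normalize(e2)$startA, 100)
  # already ordered, and fully identical loci, stay as given
  e3 <- entries_df(100, 200, 100, 200)
  expect_identical(pgl_normalize(e3), e3)
})

test_that("entry comparison sorts on all six columns and ignores annotations", {
  a <- entries_df(100, 200, 500, 600)
  b <- entries_df(100, 200, 400, 450)
  expect_equal(pgl_entry_compare(a, b), 1L)
  expect_equal(pgl_entry_compare(entries_df(1, 2, 3, 4, chromA = "chr10"),
                                 entries_df(1, 2, 3, 4, chromA = "chr7")), -1L)
  a$annotations <- "x"; b2 <- a; b2$annotations <- "y"
  expect_equal(pgl_entry_compare(a, b2), 0L)
})

test_that("entry comparison agrees with the radix sort order", {
  f <- pgl_fixture(120, seed = 19)
  e <- as.data.frame(f)
  cmp <- pgl_entry_compare(e[-nrow(e), ], e[-1, ])
  expect_true(all(cmp <= 0L))
})

test_that("pgl construction validates coordinates", {
  expect_error(pgl(entries_df(-1, 10, 20, 30)), "negative")
  expect_error(pgl(entries_df(10, 5, 20, 30)), "precedes")
  expect_silent(pgl(entries_df(10, 10, 20, 30))) # zero-length allowed
})

test_that("region parsing accepts strings and lists and rejects junk", {
  r <- parse_region("chr1:100-2000")
  expect_equal(r, list(chrom = "chr1", start = 100L, end = 2000L))
  expect_equal(parse_region(list(chrom = "chrX", start = 5, end = 9))$chrom, "chrX")
  expect_error(parse_region("chr1:2000-100"), "invalid")
  expect_error(parse_region("nonsense"), "cannot parse")
})
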
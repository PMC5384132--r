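# Ordering semantics.  All chromosome comparisons are byte-wise
# (C-locale lexicographic), never locale collation, so that e.g.
# chr1 < chr10 < chr15 < chr22 < chr7 < chrX < chrY holds everywhere.

str_cmp1 <- function(a, b) {
  if (identical(a, b)) return(0L)
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n > 0L) {
    d <- which(ra[seq_len(n)] != rb[seq_len(n)])
    if (length(d)) {
      k <- d[1L]
      return(if (ra[k] < rb[k]) -1L else 1L)
    }
  }
  if (length(ra) < length(rb)) -1L else 1L
}

#' Compare chromosome names
#'
#' Pure byte-lexicographic comparison of the full chromosome strings (no
#' natural-number parsing), giving the order chr1, chr10, chr15, chr22,
#' chr7, chrX, chrY.  Vectorised with recycling.
#'
#' @param a,b character vectors of chromosome names
#' @return integer vector: -1 (a < b), 0 (equal) or 1 (a > b)
#' @examples
#' chrom_compare("chr1", "chr10")   # -1
#' chrom_compare("chr22", "chr7")   # -1
#' @export
chrom_compare <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in which(a != b)) out[i] <- str_cmp1(a[i], b[i])
  out
}

#' Overlap test for single loci
#'
#' Half-open interval overlap on the same chromosome: true iff the
#' chromosomes are byte-equal and `start1 < end2 && start2 < end1`.
#' Zero-length loci overlap nothing; abutting intervals do not overlap.
#' Vectorised with recycling.
#'
#' @param chrom1,start1,end1 first locus
#' @param chrom2,start2,end2 second locus
#' @return logical vector
#' @export
locus_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  chrom1 == chrom2 & start1 < end2 & start2 < end1 &
    start1 < end1 & start2 < end2   # zero-length loci overlap nothing
}

#' Distance between single loci
#'
#' 0 if the loci overlap (or abut), the intervening gap in bases otherwise,
#' and `Inf` when the chromosomes differ.
#'
#' @inheritParams locus_overlap
#' @return numeric vector (0, positive gap, or Inf)
#' @export
locus_distance <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ifelse(chrom1 != chrom2, Inf,
         pmax(0, pmax(start1, start2) - pmin(end1, end2)))
}

#' Pairwise overlap test for PGL entries
#'
#' Two entries overlap iff their A loci overlap AND their B loci overlap
#' (2D overlap: both anchors).
#'
#' @param a,b data.frames with the six coordinate columns (`chromA`,
#'   `startA`, `endA`, `chromB`, `startB`, `endB`); rows are compared
#'   pairwise with recycling of single rows.
#' @return logical vector
#' @export
pgl_entry_overlap <- function(a, b) {
  locus_overlap(a$chromA, a$startA, a$endA, b$chromA, b$startA, b$endA) &
    locus_overlap(a$chromB, a$startB, a$endB, b$chromB, b$startB, b$endB)
}

#' Distance between PGL entries
#'
#' Sum of the per-anchor gaps (`locus_distance` at A plus at B); `Inf` if
#' either anchor pair lies on different chromosomes.  Zero exactly when the
#' entries overlap or abut at both anchors.
#'
#' @inheritParams pgl_entry_overlap
#' @return numeric vector
#' @export
pgl_entry_distance <- function(a, b) {
  locus_distance(a$chromA, a$startA, a$endA, b$chromA, b$startA, b$endA) +
    locus_distance(a$chromB, a$startB, a$endB, b$chromB, b$startB, b$endB)
}

#' Compare PGL entries under file-sort order
#'
#' Lexicographic over (chromA, startA, endA, chromB, startB, endB) with
#' chromosomes compared byte-wise; annotations are ignored.
#'
#' @inheritParams pgl_entry_overlap
#' @return integer vector: -1, 0 or 1
#' @export
pgl_entry_compare <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  out <- chrom_compare(a$chromA[ai], b$chromA[bi])
  tie <- out == 0L
  num_tiebreak <- function(out, tie, x, y) {
    d <- sign(x - y)
    out[tie] <- d[tie]
    list(out = out, tie = tie & d == 0L)
  }
  s <- num_tiebreak(out, tie, a$startA[ai], b$startA[bi])
  s <- num_tiebreak(s$out, s$tie, a$endA[ai], b$endA[bi])
  cb <- chrom_compare(a$chromB[ai], b$chromB[bi])
  s$out[s$tie] <- cb[s$tie]
  s$tie <- s$tie & cb == 0L
  s <- num_tiebreak(s$out, s$tie, a$startB[ai], b$startB[bi])
  s <- num_tiebreak(s$out, s$tie, a$endB[ai], b$endB[bi])
  as.integer(s$out)
}

# radix order of entries under file-sort order (stable, byte-wise)
entry_order <- function(e) {
  order(e$chromA, e$startA, e$endA, e$chromB, e$startB, e$endB,
        method = "radix")
}

#' Enforce the locus-A-before-locus-B invariant
#'
#' Every PGL entry must have its two loci assigned so that locus A
#' precedes-or-equals locus B (chromosome byte-lexicographically, then
#' start, then end).  Rows violating this have their loci swapped;
#' annotations are untouched.  Idempotent.  Fully identical loci keep
#' their given order.
#'
#' @param x a `pgl` object or an entries data.frame
#' @return object of the same kind with the invariant enforced
#' @export
pgl_normalize <- function(x) {
  if (is_pgl(x)) {
    e <- x$entries
    e2 <- pgl_normalize(e)
    return(pgl(e2, headers = x$headers, sorted = "unverified"))
  }
  e <- x
  if (!nrow(e)) return(e)
  cc <- chrom_compare(e$chromA, e$chromB)
  swap <- cc > 0L |
    (cc == 0L & (e$startA > e$startB |
                   (e$startA == e$startB & e$endA > e$endB)))
  if (any(swap)) {
    tmp <- e[swap, c("chromA", "startA", "endA"), drop = FALSE]
    e[swap, c("chromA", "startA", "endA")] <-
      e[swap, c("chromB", "startB", "endB"), drop = FALSE]
    e[swap, c("chromB", "startB", "endB")] <- tmp
  }
  e
}

# TRUE for rows violating A-before-B
ab_violations <- function(e) {
  if (!nrow(e)) return(logical(0))
  cc <- chrom_compare(e$chromA, e$chromB)
  cc > 0L | (cc == 0L & (e$startA > e$startB |
                           (e$startA == e$startB & e$endA > e$endB)))
}

#' Sort a PGL object into file order
#'
#' Stable sort under the file-sort order (chromA, startA, endA, chromB,
#' startB, endB); equal keys keep their input order.  The result is marked
#' verified-sorted.
#'
#' @param x a `pgl` object
#' @return sorted `pgl` object
#' @export
pgl_sort <- function(x) {
  stopifnot(is_pgl(x))
  e <- x$entries[entry_order(x$entries), , drop = FALSE]
  pgl(e, headers = x$headers, sorted = "verified")
}

#' Verify the sortedness of a PGL object
#'
#' Checks file-sort order and (optionally) the A-before-B entry invariant.
#' On success the object is returned marked verified-sorted; on failure an
#' error names the first offending entry.
#'
#' @param x a `pgl` object
#' @param check_ab also check the locus-A-before-locus-B invariant
#' @return `x` marked `"verified"`
#' @export
pgl_verify_sorted <- function(x, check_ab = TRUE) {
  stopifnot(is_pgl(x))
  e <- x$entries
  if (check_ab) {
    bad <- which(ab_violations(e))
    if (length(bad))
      stop("entry ", bad[1], ": locus A does not precede locus B")
  }
  n <- nrow(e)
  if (n > 1L) {
    ord <- entry_order(e)
    if (!identical(ord, seq_len(n))) {
      cmp <- pgl_entry_compare(e[-n, , drop = FALSE], e[-1L, , drop = FALSE])
      bad <- which(cmp > 0L)[1]
      stop("file not sorted: entry ", bad + 1L,
           " precedes entry ", bad, " under file-sort order; run sort first")
    }
  }
  attr(x, "sorted") <- "verified"
  x
}

# ops that require sorted input call this; verified objects pass through
assert_sorted <- function(x, what = "input") {
  if (pgl_sortedness(x) == "verified") return(x)
  tryCatch(pgl_verify_sorted(x),
           error = function(e) stop(what, ": ", conditionMessage(e), call. = FALSE))
}

# BED sortedness (chrom byte-lex, start, end)
bed_order <- function(r) order(r$chrom, r$start, r$end, method = "radix")

#' Sort a BED object
#' @param x a `bed` object
#' @return sorted `bed` object (chrom byte-lexicographic, start, end)
#' @export
bed_sort <- function(x) {
  stopifnot(is_bed(x))
  bed(x$records[bed_order(x$records), , drop = FALSE], sorted = "verified")
}

assert_bed_sorted <- function(x, what = "bed input") {
  if (attr(x, "sorted") == "verified") return(x)
  r <- x$records
  if (nrow(r) > 1L && !identical(bed_order(r), seq_len(nrow(r))))
    stop(what, ": records not sorted (chrom, start, end); run sort first",
         call. = FALSE)
  attr(x, "sorted") <- "verified"
  x
}
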
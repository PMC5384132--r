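# Mixed PGL x BED operations: single-locus genomic metadata (chromatin
# states, motifs, coding regions ...) analysed against both anchors of
# paired entries.

# indices of bed records overlapping the locus (brute per-locus test)
bed_hits <- function(r, chrom, start, end) {
  which(r$chrom == chrom & r$start < end & start < r$end)
}

# payload used when annotating: BED column 4 if present, else coordinates
bed_payload <- function(r, idx) {
  vapply(idx, function(i) {
    if (nzchar(r$annotations[i])) {
      strsplit(r$annotations[i], "\t", fixed = TRUE)[[1]][1]
    } else {
      sprintf("%s:%d-%d", r$chrom[i], r$start[i], r$end[i])
    }
  }, character(1))
}

#' Intersect a PGL file with BED regions
#'
#' Modes:
#' \describe{
#'   \item{`"either"`}{(default) keep entries where at least one locus
#'     overlaps at least one BED region.}
#'   \item{`"anchorA"`, `"anchorB"`}{restrict the tested locus.}
#'   \item{`"annotate"`}{keep all entries and append two annotation
#'     columns: the comma-joined BED payloads (column 4, or
#'     `chrom:start-end` when absent) overlapping locus A and locus B
#'     respectively, `"."` when none.}
#' }
#'
#' @param file sorted `pgl` object
#' @param bedobj sorted `bed` object
#' @param mode one of `"either"`, `"anchorA"`, `"anchorB"`, `"annotate"`
#' @return a `pgl` object
#' @export
pgl_intersect1d <- function(file, bedobj,
                            mode = c("either", "anchorA", "anchorB", "annotate")) {
  mode <- match.arg(mode)
  file <- assert_sorted(file, "PGL input")
  bedobj <- assert_bed_sorted(bedobj)
  e <- file$entries
  r <- bedobj$records
  hitsA <- lapply(seq_len(nrow(e)), function(i)
    bed_hits(r, e$chromA[i], e$startA[i], e$endA[i]))
  hitsB <- lapply(seq_len(nrow(e)), function(i)
    bed_hits(r, e$chromB[i], e$startB[i], e$endB[i]))
  if (mode == "annotate") {
    lab <- function(hits) {
      vapply(hits, function(ix) {
        if (!length(ix)) "." else paste(bed_payload(r, ix), collapse = ",")
      }, character(1))
    }
    e$annotations <- append_ann(e$annotations,
                                paste(lab(hitsA), lab(hitsB), sep = "\t"))
    return(pgl(e, headers = file$headers, sorted = "verified"))
  }
  keep <- switch(mode,
                 either = lengths(hitsA) > 0L | lengths(hitsB) > 0L,
                 anchorA = lengths(hitsA) > 0L,
                 anchorB = lengths(hitsB) > 0L)
  subset_pgl(file, which(keep), sorted = "verified")
}

#' Closest BED region for each PGL entry
#'
#' For each entry, finds the BED record minimizing
#' `min(locus_distance(A, r), locus_distance(B, r))`.  All ties are
#' emitted, in BED input order; the record's three coordinates and
#' annotations are appended, then the distance.  Entries with no
#' finite-distance candidate get three `"."` placeholders and distance -1.
#'
#' @param file sorted `pgl` object
#' @param bedobj sorted `bed` object
#' @return a `pgl` object
#' @export
pgl_closest1d <- function(file, bedobj) {
  file <- assert_sorted(file, "PGL input")
  bedobj <- assert_bed_sorted(bedobj)
  e <- file$entries
  r <- bedobj$records
  rows <- list()
  for (i in seq_len(nrow(e))) {
    base <- e[i, , drop = FALSE]
    if (nrow(r)) {
      dA <- locus_distance(e$chromA[i], e$startA[i], e$endA[i],
                           r$chrom, r$start, r$end)
      dB <- locus_distance(e$chromB[i], e$startB[i], e$endB[i],
                           r$chrom, r$start, r$end)
      d <- pmin(dA, dB)
    } else {
      d <- numeric(0)
    }
    finite <- is.finite(d)
    if (!any(finite)) {
      base$annotations <- append_ann(base$annotations,
                                     paste(".", ".", ".", "-1", sep = "\t"))
      rows[[length(rows) + 1L]] <- base
      next
    }
    dm <- min(d[finite])
    for (j in which(finite & d == dm)) {
      out <- base
      extra <- paste(r$chrom[j], r$start[j], r$end[j], sep = "\t")
      if (nzchar(r$annotations[j]))
        extra <- paste(extra, r$annotations[j], sep = "\t")
      extra <- paste(extra, format(dm, scientific = FALSE), sep = "\t")
      out$annotations <- append_ann(out$annotations, extra)
      rows[[length(rows) + 1L]] <- out
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  pgl(out, headers = file$headers, sorted = "verified")
}

# 1D difference: interval (s, e) minus the union of bed intervals on chrom;
# returns data.frame of fragments (possibly empty)
interval_diff_1d <- function(chrom, s, e, r) {
  hits <- bed_hits(r, chrom, s, e)
  if (!length(hits)) return(data.frame(start = s, end = e))
  iv <- data.frame(start = pmax(r$start[hits], s), end = pmin(r$end[hits], e))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  frags <- list()
  cur <- s
  for (k in seq_len(nrow(iv))) {
    if (iv$start[k] > cur) frags[[length(frags) + 1L]] <- c(cur, iv$start[k])
    cur <- max(cur, iv$end[k])
  }
  if (cur < e) frags[[length(frags) + 1L]] <- c(cur, e)
  if (!length(frags)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, frags)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Subtract BED regions from both loci of a PGL file
#'
#' For each entry, locus A minus the union of BED regions yields fragments
#' a1..an and locus B likewise b1..bm; the cross product (ai, bj) is
#' emitted with the original annotations.  An entry is dropped when either
#' locus is fully covered; entries untouched by any region pass through
#' unchanged.  Output is sorted.
#'
#' @param file sorted `pgl` object
#' @param bedobj sorted `bed` object
#' @return a sorted `pgl` object
#' @export
pgl_subtract1d <- function(file, bedobj) {
  file <- assert_sorted(file, "PGL input")
  bedobj <- assert_bed_sorted(bedobj)
  e <- file$entries
  r <- bedobj$records
  rows <- list()
  for (i in seq_len(nrow(e))) {
    fa <- interval_diff_1d(e$chromA[i], e$startA[i], e$endA[i], r)
    if (!nrow(fa)) next
    fb <- interval_diff_1d(e$chromB[i], e$startB[i], e$endB[i], r)
    if (!nrow(fb)) next
    grid <- expand.grid(ka = seq_len(nrow(fa)), kb = seq_len(nrow(fb)))
    rows[[length(rows) + 1L]] <- data.frame(
      chromA = e$chromA[i], startA = fa$start[grid$ka], endA = fa$end[grid$ka],
      chromB = e$chromB[i], startB = fb$start[grid$kb], endB = fb$end[grid$kb],
      annotations = e$annotations[i], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  # entries whose anchors overlap each other can yield fragments with the
  # loci out of order; restore the A-before-B invariant before sorting
  pgl_sort(pgl(pgl_normalize(out), headers = file$headers))
}
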
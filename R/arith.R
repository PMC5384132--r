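# Pairwise 2D genomic arithmetic on sorted PGL files.

#' Intersect two PGL files
#'
#' Overlap is pair-aware: two entries match only when BOTH anchors overlap.
#' Modes:
#' \describe{
#'   \item{`"intersection"`}{(default) for each overlapping pair, the
#'     per-locus interval intersections (max of starts, min of ends), with
#'     file-1 then file-2 annotations carried along.}
#'   \item{`"report-a"`}{each file-1 entry once per overlap, unchanged.}
#'   \item{`"append-b"`}{each file-1 entry once per overlap, with the
#'     matching file-2 entry's six coordinates and annotations appended as
#'     annotation columns.}
#'   \item{`"unique"`}{each file-1 entry with at least one overlap, once.}
#'   \item{`"no-overlap"`}{file-1 entries with zero overlaps.}
#'   \item{`"base-counts"`}{the intersection entries with two appended
#'     annotation columns: the overlapping base count at locus A and at
#'     locus B.}
#' }
#'
#' @param file1,file2 sorted `pgl` objects
#' @param mode one of the modes above
#' @return a sorted `pgl` object
#' @export
pgl_intersect <- function(file1, file2,
                          mode = c("intersection", "report-a", "append-b",
                                   "unique", "no-overlap", "base-counts")) {
  mode <- match.arg(mode)
  ov <- pgl_find_overlaps(file1, file2)
  e1 <- file1$entries
  e2 <- file2$entries
  if (mode == "no-overlap") {
    keep <- setdiff(seq_len(nrow(e1)), unique(ov$idx1))
    return(subset_pgl(file1, sort(keep), sorted = "verified"))
  }
  if (mode == "unique") {
    return(subset_pgl(file1, sort(unique(ov$idx1)), sorted = "verified"))
  }
  if (mode == "report-a") {
    out <- e1[ov$idx1, , drop = FALSE]
    return(pgl_sort(pgl(out, headers = file1$headers)))
  }
  if (mode == "append-b") {
    out <- e1[ov$idx1, , drop = FALSE]
    b <- e2[ov$idx2, , drop = FALSE]
    extra <- paste(b$chromA, b$startA, b$endA, b$chromB, b$startB, b$endB,
                   sep = "\t")
    has_ann <- nzchar(b$annotations)
    extra[has_ann] <- paste(extra[has_ann], b$annotations[has_ann], sep = "\t")
    out$annotations <- append_ann(out$annotations, extra)
    return(pgl_sort(pgl(out, headers = file1$headers)))
  }
  a <- e1[ov$idx1, , drop = FALSE]
  b <- e2[ov$idx2, , drop = FALSE]
  inter <- data.frame(chromA = a$chromA,
                      startA = pmax(a$startA, b$startA),
                      endA = pmin(a$endA, b$endA),
                      chromB = a$chromB,
                      startB = pmax(a$startB, b$startB),
                      endB = pmin(a$endB, b$endB),
                      annotations = append_ann(a$annotations, ifelse(
                        nzchar(b$annotations), b$annotations, "")),
                      stringsAsFactors = FALSE)
  inter$annotations <- sub("\t$", "", inter$annotations)
  if (mode == "base-counts") {
    counts <- paste(inter$endA - inter$startA, inter$endB - inter$startB,
                    sep = "\t")
    inter$annotations <- append_ann(inter$annotations, counts)
  }
  pgl_sort(pgl(inter, headers = file1$headers))
}

#' Merge nearby entries within one PGL file
#'
#' Entries whose pairwise distance ([pgl_entry_distance()], the sum of the
#' per-anchor gaps) is at most `distance` are grouped into connected
#' components; because merged bounding boxes grow, the grouping is iterated
#' against the growing boxes until a fixpoint.  Each component emits one
#' entry whose loci are the bounding intervals (min start, max end) of the
#' member loci.  Components never span chromosomes (cross-chromosome
#' distance is infinite).  Requested summary statistics over member
#' annotation columns are appended in order.
#'
#' @param file sorted `pgl` object
#' @param distance non-negative gap allowance in bases (0 merges only
#'   touching/overlapping entries)
#' @param stat_cols integer vector of 1-based FILE column numbers (>= 7,
#'   i.e. annotation columns) over which to compute statistics; `count`
#'   accepts any column
#' @param stat_ops character vector, same length as `stat_cols`, each one
#'   of `"count"`, `"sum"`, `"min"`, `"max"`, `"mean"`, `"collapse"`,
#'   `"distinct"`
#' @return a sorted `pgl` object of merged entries
#' @export
pgl_merge <- function(file, distance = 0L, stat_cols = integer(0),
                      stat_ops = character(0)) {
  file <- assert_sorted(file, "input")
  if (length(stat_cols) != length(stat_ops))
    stop("stat_cols and stat_ops must have the same length")
  if (distance < 0) stop("distance must be non-negative")
  ok_ops <- c("count", "sum", "min", "max", "mean", "collapse", "distinct")
  bad <- setdiff(stat_ops, ok_ops)
  if (length(bad)) stop("unknown summary operation: ", bad[1])
  e <- file$entries
  n <- nrow(e)
  if (!n) return(pgl(headers = file$headers, sorted = "verified"))

  key <- paste(e$chromA, e$chromB, sep = "\r")
  comp_rows <- list()
  for (grp in split(seq_len(n), key)) {
    boxes <- data.frame(sa = e$startA[grp], ea = e$endA[grp],
                        sb = e$startB[grp], eb = e$endB[grp])
    members <- as.list(grp)
    repeat {
      m <- nrow(boxes)
      if (m <= 1L) break
      parent <- seq_len(m)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      merged_any <- FALSE
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          gap <- max(0, max(boxes$sa[i], boxes$sa[j]) -
                       min(boxes$ea[i], boxes$ea[j])) +
            max(0, max(boxes$sb[i], boxes$sb[j]) -
                  min(boxes$eb[i], boxes$eb[j]))
          if (gap <= distance) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged_any <- TRUE }
          }
        }
      }
      if (!merged_any) break
      roots <- vapply(seq_len(m), find, integer(1))
      idx <- split(seq_len(m), roots)
      boxes <- do.call(rbind, lapply(idx, function(ix) {
        data.frame(sa = min(boxes$sa[ix]), ea = max(boxes$ea[ix]),
                   sb = min(boxes$sb[ix]), eb = max(boxes$eb[ix]))
      }))
      members <- lapply(idx, function(ix) sort(unlist(members[ix])))
      rownames(boxes) <- NULL
    }
    chromA <- e$chromA[grp[1]]
    chromB <- e$chromB[grp[1]]
    for (k in seq_along(members)) {
      comp_rows[[length(comp_rows) + 1L]] <- list(
        chromA = chromA, sa = boxes$sa[k], ea = boxes$ea[k],
        chromB = chromB, sb = boxes$sb[k], eb = boxes$eb[k],
        members = members[[k]])
    }
  }

  ann <- vapply(comp_rows, function(cr) {
    if (!length(stat_ops)) return("")
    stats <- mapply(function(colno, op) {
      if (op == "count") return(as.character(length(cr$members)))
      k <- colno - 6L
      if (k < 1L) stop("stat column must be a file column >= 7")
      vals <- ann_field(e$annotations[cr$members], k, what = "merged member")
      switch(op,
             sum = format(sum(as.numeric(vals)), scientific = FALSE),
             min = format(min(as.numeric(vals)), scientific = FALSE),
             max = format(max(as.numeric(vals)), scientific = FALSE),
             mean = format(mean(as.numeric(vals)), scientific = FALSE),
             collapse = paste(vals, collapse = ","),
             distinct = paste(unique(vals), collapse = ","))
    }, stat_cols, stat_ops)
    paste(stats, collapse = "\t")
  }, character(1))

  out <- data.frame(
    chromA = vapply(comp_rows, `[[`, character(1), "chromA"),
    startA = vapply(comp_rows, `[[`, numeric(1), "sa"),
    endA = vapply(comp_rows, `[[`, numeric(1), "ea"),
    chromB = vapply(comp_rows, `[[`, character(1), "chromB"),
    startB = vapply(comp_rows, `[[`, numeric(1), "sb"),
    endB = vapply(comp_rows, `[[`, numeric(1), "eb"),
    annotations = ann, stringsAsFactors = FALSE)
  pgl_sort(pgl(out, headers = file$headers))
}

# guillotine 2D difference of one rectangle minus one overlapping rectangle:
# A-left and A-right strips carry the full B interval; the A-overlap strip
# carries the B remainders
cut_rect <- function(fr, sa, ea, sb, eb) {
  out <- list()
  ia_s <- max(fr$sa, sa); ia_e <- min(fr$ea, ea)
  if (fr$sa < ia_s) out[[length(out) + 1L]] <- list(sa = fr$sa, ea = ia_s, sb = fr$sb, eb = fr$eb)
  if (fr$ea > ia_e) out[[length(out) + 1L]] <- list(sa = ia_e, ea = fr$ea, sb = fr$sb, eb = fr$eb)
  if (fr$sb < sb) out[[length(out) + 1L]] <- list(sa = ia_s, ea = ia_e, sb = fr$sb, eb = min(fr$eb, sb))
  if (fr$eb > eb) out[[length(out) + 1L]] <- list(sa = ia_s, ea = ia_e, sb = max(fr$sb, eb), eb = fr$eb)
  out
}

#' Subtract one PGL file from another
#'
#' Each file-1 entry is treated as an axis-aligned rectangle in the
#' (locus A coordinate) x (locus B coordinate) plane; the union of all
#' 2D-overlapping file-2 rectangles is removed and the remainder is
#' decomposed into rectangles by guillotine cuts along the A axis first.
#' Fragments inherit the original annotations; entries with no overlap
#' pass through unchanged.  An entry fully covered at both loci is removed
#' entirely; overlap at only one locus leaves the entry untouched (2D
#' overlap requires both anchors).
#'
#' @param file1,file2 sorted `pgl` objects
#' @return a sorted `pgl` object of remainder fragments
#' @export
pgl_subtract <- function(file1, file2) {
  ov <- pgl_find_overlaps(file1, file2)
  e1 <- file1$entries
  e2 <- file2$entries
  by1 <- split(ov$idx2, ov$idx1)
  rows <- list()
  for (i in seq_len(nrow(e1))) {
    js <- by1[[as.character(i)]]
    if (is.null(js)) {
      rows[[length(rows) + 1L]] <- e1[i, , drop = FALSE]
      next
    }
    frags <- list(list(sa = e1$startA[i], ea = e1$endA[i],
                       sb = e1$startB[i], eb = e1$endB[i]))
    for (j in js) {
      nxt <- list()
      for (fr in frags) {
        if (fr$sa < e2$endA[j] && e2$startA[j] < fr$ea &&
            fr$sb < e2$endB[j] && e2$startB[j] < fr$eb) {
          nxt <- c(nxt, cut_rect(fr, e2$startA[j], e2$endA[j],
                                 e2$startB[j], e2$endB[j]))
        } else {
          nxt <- c(nxt, list(fr))
        }
      }
      frags <- nxt
      if (!length(frags)) break
    }
    for (fr in frags) {
      rows[[length(rows) + 1L]] <- data.frame(
        chromA = e1$chromA[i], startA = fr$sa, endA = fr$ea,
        chromB = e1$chromB[i], startB = fr$sb, endB = fr$eb,
        annotations = e1$annotations[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  # entries whose anchors overlap each other can yield fragments with the
  # loci out of order; restore the A-before-B invariant before sorting
  pgl_sort(pgl(pgl_normalize(out), headers = file1$headers))
}

#' Filter a PGL file to a genomic region
#'
#' Keeps entries whose selected loci fall completely within the region
#' (same chromosome, `region.start <= locus.start` and
#' `locus.end <= region.end`).
#'
#' @param file sorted `pgl` object
#' @param region `"chrom:start-end"` string or list(chrom, start, end)
#' @param mode `"both"` (A and B contained), `"either"` (at least one),
#'   `"anchorA"`, or `"anchorB"`
#' @return a `pgl` object of the retained entries (input order, which is
#'   sorted when the input is)
#' @export
pgl_window <- function(file, region, mode = c("both", "either", "anchorA", "anchorB")) {
  mode <- match.arg(mode)
  stopifnot(is_pgl(file))
  r <- parse_region(region)
  e <- file$entries
  inA <- e$chromA == r$chrom & e$startA >= r$start & e$endA <= r$end
  inB <- e$chromB == r$chrom & e$startB >= r$start & e$endB <= r$end
  keep <- switch(mode, both = inA & inB, either = inA | inB,
                 anchorA = inA, anchorB = inB)
  subset_pgl(file, which(keep), sorted = pgl_sortedness(file))
}

#' Coverage of one PGL file on another
#'
#' Emits every file-1 entry with one appended annotation column: the number
#' of file-2 entries overlapping it at both anchors (any overlap;
#' containment not required; file-2 multiplicity counts).  Typically used
#' with read pairs from [sam_to_pgl()] as file 2.
#'
#' @param file1,file2 sorted `pgl` objects
#' @return a sorted `pgl` object (file 1 with the count column)
#' @export
pgl_coverage <- function(file1, file2) {
  ov <- pgl_find_overlaps(file1, file2)
  e <- file1$entries
  counts <- integer(nrow(e))
  if (nrow(ov)) {
    tab <- table(ov$idx1)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  e$annotations <- append_ann(e$annotations, as.character(counts))
  pgl(e, headers = file1$headers, sorted = "verified")
}

#' Closest entry in another PGL file
#'
#' For each file-1 entry, finds the file-2 entry (or entries) minimizing
#' [pgl_entry_distance()] (sum of per-anchor gaps).  All ties are emitted
#' as separate lines, in file-2 order.  The matching entry's six
#' coordinates and annotations are appended, followed by the distance.
#' When no file-2 entry is at finite distance, six `"."` placeholder
#' columns and distance `-1` are appended.
#'
#' @param file1,file2 sorted `pgl` objects
#' @return a sorted `pgl` object
#' @export
pgl_closest <- function(file1, file2) {
  file1 <- assert_sorted(file1, "file 1")
  file2 <- assert_sorted(file2, "file 2")
  e1 <- file1$entries
  e2 <- file2$entries
  rows <- list()
  for (i in seq_len(nrow(e1))) {
    base <- e1[i, , drop = FALSE]
    if (nrow(e2)) {
      d <- pgl_entry_distance(base, e2)
    } else {
      d <- numeric(0)
    }
    finite <- is.finite(d)
    if (!any(finite)) {
      base$annotations <- append_ann(base$annotations,
                                     paste(".", ".", ".", ".", ".", ".", "-1",
                                           sep = "\t"))
      rows[[length(rows) + 1L]] <- base
      next
    }
    dm <- min(d[finite])
    hits <- which(finite & d == dm)
    for (j in hits) {
      out <- base
      extra <- paste(e2$chromA[j], e2$startA[j], e2$endA[j],
                     e2$chromB[j], e2$startB[j], e2$endB[j], sep = "\t")
      if (nzchar(e2$annotations[j]))
        extra <- paste(extra, e2$annotations[j], sep = "\t")
      extra <- paste(extra, format(dm, scientific = FALSE), sep = "\t")
      out$annotations <- append_ann(out$annotations, extra)
      rows[[length(rows) + 1L]] <- out
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_entries()
  pgl(out, headers = file1$headers, sorted = "verified")
}

#' Expand both loci of every entry
#'
#' Each locus start is reduced by `pad` (floored at 0) and each end
#' increased by `pad`.  The A-before-B invariant is re-checked and the
#' output re-sorted.
#'
#' @param file a `pgl` object
#' @param pad non-negative number of bases
#' @return a sorted `pgl` object
#' @export
pgl_expand <- function(file, pad) {
  stopifnot(is_pgl(file))
  if (length(pad) != 1L || is.na(pad) || pad < 0) stop("pad must be non-negative")
  pad <- as.integer(pad)
  e <- file$entries
  e$startA <- pmax(0L, e$startA - pad)
  e$endA <- e$endA + pad
  e$startB <- pmax(0L, e$startB - pad)
  e$endB <- e$endB + pad
  pgl_sort(pgl(pgl_normalize(e), headers = file$headers))
}
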
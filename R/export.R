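# Exporters to visualization and downstream-analysis formats.

default_color <- c(0L, 0L, 255L)

check_color <- function(color) {
  color <- as.integer(color)
  if (length(color) != 3L || anyNA(color) || any(color < 0L) || any(color > 255L))
    stop("color must be three integers in 0-255")
  color
}

score_values <- function(x, score_col, what) {
  if (is.null(score_col)) return(rep(0, pgl_length(x)))
  k <- as.integer(score_col) - 6L
  if (is.na(k) || k < 1L) stop("score column must be a file column >= 7")
  vals <- ann_field(x$entries$annotations, k, what = what)
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    i <- which(is.na(num))[1]
    stop(sprintf("%s %d: annotation column %d value '%s' is not numeric",
                 what, i, score_col, vals[i]))
  }
  num
}

#' Format a PGL file as a UCSC Genome Browser track
#'
#' Emits a `track` header line followed by one BED12 line per
#' intra-chromosomal entry: the record spans from the start of anchor A to
#' the end of anchor B with the two anchors as blocks
#' (`blockCount = 2`, `blockSizes = lenA,lenB`,
#' `blockStarts = 0,(startB - startA)`).  Inter-chromosomal entries cannot
#' be drawn as a single-chromosome record and are skipped, as are entries
#' whose anchors overlap (`endA > startB`, not representable as BED12
#' blocks); skip counts are reported as warnings.  Scores come from an
#' optional numeric annotation column, rounded and clamped to 0-1000.
#'
#' @param x a `pgl` object
#' @param track_name track name shown in the browser
#' @param color RGB triple (0-255 each) for `itemRgb`
#' @param score_col optional 1-based file column number (>= 7) of a numeric
#'   annotation used as the BED score
#' @return character vector of output lines
#' @export
pgl_to_browser <- function(x, track_name = "pgl", color = default_color,
                           score_col = NULL) {
  stopifnot(is_pgl(x))
  color <- check_color(color)
  e <- x$entries
  score <- score_values(x, score_col, "entry")
  track <- sprintf('track name="%s" itemRgb="On"', track_name)
  inter <- e$chromA != e$chromB
  if (any(inter)) warning(sum(inter), " inter-chromosomal entr(ies) skipped")
  degen <- !inter & e$endA > e$startB
  if (any(degen))
    warning(sum(degen), " entr(ies) with overlapping anchors skipped (not representable as BED12 blocks)")
  keep <- which(!inter & !degen)
  if (!length(keep)) return(track)
  e <- e[keep, , drop = FALSE]
  score <- pmin(1000, pmax(0, round(score[keep])))
  rgb <- paste(color, collapse = ",")
  lines <- sprintf("%s\t%d\t%d\tPGL_%d\t%d\t.\t%d\t%d\t%s\t2\t%d,%d\t0,%d",
                   e$chromA, e$startA, e$endB, keep, score,
                   e$startA, e$endB, rgb,
                   e$endA - e$startA, e$endB - e$startB,
                   e$startB - e$startA)
  c(track, lines)
}

#' Format a PGL file as Juicebox 2D annotations
#'
#' Seven tab-separated columns
#' (`chromosome1 x1 x2 chromosome2 y1 y2 color`) with the color written as
#' `"R,G,B"`.  Inter-chromosomal entries are included (the format is 2D).
#'
#' @param x a `pgl` object
#' @param color RGB triple (0-255 each)
#' @return character vector of output lines (header first)
#' @export
pgl_to_juicebox <- function(x, color = default_color) {
  stopifnot(is_pgl(x))
  color <- check_color(color)
  header <- paste("chromosome1", "x1", "x2", "chromosome2", "y1", "y2",
                  "color", sep = "\t")
  e <- x$entries
  if (!nrow(e)) return(header)
  rgb <- paste(color, collapse = ",")
  c(header, paste(e$chromA, e$startA, e$endA, e$chromB, e$startB, e$endB,
                  rgb, sep = "\t"))
}

#' Format a PGL file as 10-column bedpe for interaction analysis packages
#'
#' Emits `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`
#' lines, ingestible by bedpe importers such as the GenomicInteractions
#' package.  Names are `PGL_1..PGL_n`; strands are `"."`; the score is 0
#' or taken from a numeric annotation column.
#'
#' @param x a `pgl` object
#' @param score_col optional 1-based file column number (>= 7) of a numeric
#'   annotation used as the score
#' @return character vector of output lines
#' @export
pgl_to_interactions <- function(x, score_col = NULL) {
  stopifnot(is_pgl(x))
  e <- x$entries
  if (!nrow(e)) return(character(0))
  score <- score_values(x, score_col, "entry")
  paste(e$chromA, e$startA, e$endA, e$chromB, e$startB, e$endB,
        paste0("PGL_", seq_len(nrow(e))),
        format(score, trim = TRUE, scientific = FALSE),
        ".", ".", sep = "\t")
}

#' Condense a PGL file to discrete anchor BED records
#'
#' Two BED records per entry (locus A and locus B), each annotated with the
#' entry identifier `PGL_<k>`; output in sorted BED order.
#'
#' @param x a `pgl` object
#' @return a sorted `bed` object with 2n records
#' @export
pgl_condense <- function(x) {
  stopifnot(is_pgl(x))
  e <- x$entries
  ids <- paste0("PGL_", seq_len(nrow(e)))
  r <- data.frame(chrom = c(e$chromA, e$chromB),
                  start = c(e$startA, e$startB),
                  end = c(e$endA, e$endB),
                  annotations = c(ids, ids), stringsAsFactors = FALSE)
  bed_sort(bed(r))
}

#' Loop-interior BED records of a PGL file
#'
#' Intra-chromosomal entries yield one record spanning from the start of
#' anchor A to the end of anchor B; inter-chromosomal entries yield one
#' record per anchor.  Records carry the entry identifier `PGL_<k>`;
#' output in sorted BED order.
#'
#' @param x a `pgl` object
#' @return a sorted `bed` object
#' @export
pgl_find_loops <- function(x) {
  stopifnot(is_pgl(x))
  e <- x$entries
  ids <- paste0("PGL_", seq_len(nrow(e)))
  intra <- e$chromA == e$chromB
  stopifnot(all(e$startA[intra] <= e$endB[intra]))
  r <- rbind(
    data.frame(chrom = e$chromA[intra], start = e$startA[intra],
               end = e$endB[intra], annotations = ids[intra],
               stringsAsFactors = FALSE),
    data.frame(chrom = e$chromA[!intra], start = e$startA[!intra],
               end = e$endA[!intra], annotations = ids[!intra],
               stringsAsFactors = FALSE),
    data.frame(chrom = e$chromB[!intra], start = e$startB[!intra],
               end = e$endB[!intra], annotations = ids[!intra],
               stringsAsFactors = FALSE))
  bed_sort(bed(r))
}
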
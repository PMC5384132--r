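# Ingest converters: bedpe, triplet sparse matrix (HiC-Pro dialect), SAM.

#' Convert a bedpe-like file to PGL
#'
#' bedpe stores the two loci in arbitrary order; each line is normalized so
#' locus A precedes locus B, annotation columns (7+) are preserved
#' verbatim, and the result is sorted into file order.  Lines whose
#' chromosome is the `"."` placeholder (unknown mate) are skipped; the skip
#' count is reported as a warning.
#'
#' @inheritParams read_pgl
#' @return a sorted `pgl` object
#' @export
format_bedpe <- function(src) {
  parts <- split_data_lines(read_source_lines(src))
  data <- parts$data
  line_no <- parts$line_no
  fields <- strsplit(data, "\t", fixed = TRUE)
  dot <- vapply(fields, function(f) length(f) >= 4L && (f[1] == "." || f[4] == "."),
                logical(1))
  if (any(dot)) {
    warning(sum(dot), " bedpe line(s) with '.' chromosome skipped")
    data <- data[!dot]
    line_no <- line_no[!dot]
  }
  e <- parse_six_plus(data, line_no, "bedpe")
  bad <- e$endA < e$startA | e$endB < e$startB
  if (any(bad)) stop("line ", line_no[which(bad)[1]], ": end precedes start")
  e <- pgl_normalize(e)
  pgl_sort(pgl(e, headers = parts$headers))
}

#' Convert a triplet sparse matrix file set to PGL
#'
#' HiC-Pro style inputs: a bin-coordinate file with lines
#' `chrom<TAB>start<TAB>end<TAB>index`, and a matrix file with triplets
#' `i<TAB>j<TAB>count`.  Each triplet becomes one PGL entry from the two
#' bins (normalized A-before-B) carrying the count verbatim as its
#' annotation; the result is sorted.
#'
#' @param matrix_src triplet matrix source (path, `"-"`, connection or lines)
#' @param bins_src bin-coordinate source
#' @return a sorted `pgl` object
#' @export
format_trip_sparse <- function(matrix_src, bins_src) {
  bparts <- split_data_lines(read_source_lines(bins_src))
  bf <- strsplit(bparts$data, "\t", fixed = TRUE)
  nf <- lengths(bf)
  if (any(nf < 4L)) {
    i <- which(nf < 4L)[1]
    stop("bin file line ", bparts$line_no[i], ": expected chrom, start, end, index")
  }
  get <- function(fl, k) vapply(fl, `[[`, character(1), k)
  idx <- parse_coord(get(bf, 4), bparts$line_no, 4L)
  if (anyDuplicated(idx)) {
    stop("duplicate bin index ", idx[anyDuplicated(idx)])
  }
  bins <- data.frame(chrom = get(bf, 1),
                     start = parse_coord(get(bf, 2), bparts$line_no, 2L),
                     end = parse_coord(get(bf, 3), bparts$line_no, 3L),
                     stringsAsFactors = FALSE)
  validate_loci(bins$chrom, bins$start, bins$end)

  mparts <- split_data_lines(read_source_lines(matrix_src))
  mf <- strsplit(mparts$data, "\t", fixed = TRUE)
  nf <- lengths(mf)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop("matrix file line ", mparts$line_no[i], ": expected i, j, count")
  }
  i_idx <- parse_coord(get(mf, 1), mparts$line_no, 1L)
  j_idx <- parse_coord(get(mf, 2), mparts$line_no, 2L)
  counts <- get(mf, 3)
  pos_i <- match(i_idx, idx)
  pos_j <- match(j_idx, idx)
  if (anyNA(pos_i)) stop("bin index ", i_idx[which(is.na(pos_i))[1]],
                         " absent from bin file")
  if (anyNA(pos_j)) stop("bin index ", j_idx[which(is.na(pos_j))[1]],
                         " absent from bin file")
  e <- data.frame(chromA = bins$chrom[pos_i], startA = bins$start[pos_i],
                  endA = bins$end[pos_i],
                  chromB = bins$chrom[pos_j], startB = bins$start[pos_j],
                  endB = bins$end[pos_j],
                  annotations = counts, stringsAsFactors = FALSE)
  pgl_sort(pgl(pgl_normalize(e)))
}

#' Reference-consumed length of a CIGAR string
#'
#' Sum of the lengths of the reference-consuming operations
#' (M, D, N, =, X); insertions and clips consume no reference.
#'
#' @param cigar character vector of CIGAR strings
#' @return integer vector of reference span lengths
#' @export
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- gregexpr("([0-9]+)([MIDNSHP=X])", cg)[[1]]
    if (m[1] == -1L) stop("malformed CIGAR '", cg, "'")
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (sum(nchar(ops)) != nchar(cg)) stop("malformed CIGAR '", cg, "'")
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kind <- substring(ops, nchar(ops))
    sum(lens[kind %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

FLAG_UNMAPPED <- 4L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

#' Convert a SAM file to PGL
#'
#' Alignments are grouped by QNAME.  Unmapped (0x4), secondary (0x100) and
#' supplementary (0x800) records are skipped, as are mapped records with
#' CIGAR `*` (with a warning).  Each QNAME with exactly two surviving mates
#' yields one entry whose loci are the reference spans
#' `[POS-1, POS-1+reference_length(CIGAR))` of the mates, normalized
#' A-before-B, annotated with the QNAME; more than two surviving mates for
#' one QNAME is an error.  The result is sorted.
#'
#' @inheritParams read_pgl
#' @return a sorted `pgl` object
#' @export
sam_to_pgl <- function(src) {
  lines <- read_source_lines(src)
  aln <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(aln)) return(pgl(sorted = "verified"))
  fields <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM alignment line with fewer than 11 fields (line ",
         which(nf < 11L)[1], " of alignment section)")
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  qname <- get(1)
  flag <- suppressWarnings(as.integer(get(2)))
  if (anyNA(flag)) stop("non-integer FLAG field in SAM input")
  rname <- get(3)
  pos <- suppressWarnings(as.integer(get(4)))
  cigar <- get(6)
  keep <- bitwAnd(flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L
  star <- keep & cigar == "*"
  if (any(star)) {
    warning(sum(star), " mapped SAM record(s) with CIGAR '*' skipped")
    keep <- keep & !star
  }
  qname <- qname[keep]; rname <- rname[keep]
  pos <- pos[keep]; cigar <- cigar[keep]
  if (!length(qname)) return(pgl(sorted = "verified"))
  if (anyNA(pos) || any(pos < 1L)) stop("invalid POS field in mapped SAM record")
  span <- cigar_ref_length(cigar)
  start <- pos - 1L
  end <- start + span
  groups <- split(seq_along(qname), qname)
  sizes <- lengths(groups)
  if (any(sizes > 2L)) {
    stop("QNAME '", names(groups)[which(sizes > 2L)[1]],
         "' has more than two primary mapped records")
  }
  pairs <- groups[sizes == 2L]
  if (!length(pairs)) return(pgl(sorted = "verified"))
  i1 <- vapply(pairs, `[[`, integer(1), 1L)
  i2 <- vapply(pairs, `[[`, integer(1), 2L)
  e <- data.frame(chromA = rname[i1], startA = start[i1], endA = end[i1],
                  chromB = rname[i2], startB = start[i2], endB = end[i2],
                  annotations = names(pairs), stringsAsFactors = FALSE)
  pgl_sort(pgl(pgl_normalize(e)))
}
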
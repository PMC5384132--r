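# Text I/O for the PGL and BED formats.
#
# Readers accept a file path, "-" for standard input, a connection, or a
# character vector of lines.  All annotation text (columns 7+ for PGL,
# 4+ for BED) is kept verbatim, so read -> write round-trips byte-exactly.
# Coordinates must match ^[0-9]+$: scientific notation or signs would not
# survive a round trip and are rejected.

read_source_lines <- function(src) {
  if (is.character(src) && length(src) == 1L &&
      !grepl("[\n\t]", src)) {
    if (src == "-") {
      con <- file("stdin")
      on.exit(close(con))
      return(readLines(con, warn = FALSE))
    }
    if (!file.exists(src)) stop("cannot open '", src, "': no such file")
    return(readLines(src, warn = FALSE))
  }
  if (inherits(src, "connection")) return(readLines(src, warn = FALSE))
  if (is.character(src)) {
    return(unlist(strsplit(src, "\n", fixed = TRUE), use.names = FALSE))
  }
  stop("unsupported input source")
}

open_sink <- function(dest) {
  if (is.null(dest)) return(list(con = stdout(), close = FALSE))
  if (inherits(dest, "connection")) return(list(con = dest, close = FALSE))
  if (is.character(dest) && length(dest) == 1L) {
    if (dest == "-") return(list(con = stdout(), close = FALSE))
    return(list(con = file(dest, open = "w"), close = TRUE))
  }
  stop("unsupported output destination")
}

parse_coord <- function(txt, line_no, col) {
  bad <- !grepl("^[0-9]+$", txt)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("line %d: non-integer coordinate '%s' in column %d",
                 line_no[i], txt[i], col))
  }
  v <- as.integer(txt)
  if (anyNA(v)) stop("coordinate overflow at line ", line_no[which(is.na(v))[1]])
  v
}

split_data_lines <- function(lines) {
  keep <- nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  is_header <- startsWith(lines, "#")
  list(headers = lines[is_header],
       data = lines[!is_header],
       line_no = line_no[!is_header])
}

parse_six_plus <- function(data, line_no, what) {
  fields <- strsplit(data, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    i <- which(nf < 6L)[1]
    stop(sprintf("line %d: %s requires at least 6 tab-separated columns, found %d",
                 line_no[i], what, nf[i]))
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  ann <- vapply(fields, function(f) {
    if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else ""
  }, character(1))
  data.frame(chromA = get(1),
             startA = parse_coord(get(2), line_no, 2L),
             endA = parse_coord(get(3), line_no, 3L),
             chromB = get(4),
             startB = parse_coord(get(5), line_no, 5L),
             endB = parse_coord(get(6), line_no, 6L),
             annotations = ann,
             stringsAsFactors = FALSE)
}

#' Read a PGL file
#'
#' Parses tab-delimited PGL text: six required coordinate columns
#' (chromA, startA, endA, chromB, startB, endB; 0-based half-open) followed
#' by any number of annotation columns, with `#`-prefixed header lines.
#' Header lines are accepted anywhere and collected; blank lines are
#' ignored.  Malformed lines (fewer than 6 columns, non-integer
#' coordinates, end < start) raise an error naming the line.
#'
#' @param src file path, `"-"` for standard input, a connection, or a
#'   character vector of lines
#' @param strict_sorted verify file-sort order and the A-before-B invariant;
#'   a violation raises a sort-order error naming the offending entry
#' @return a `pgl` object (`"verified"` if `strict_sorted`, else
#'   `"unverified"`)
#' @export
read_pgl <- function(src, strict_sorted = FALSE) {
  parts <- split_data_lines(read_source_lines(src))
  e <- parse_six_plus(parts$data, parts$line_no, "PGL")
  bad <- e$endA < e$startA
  if (any(bad)) stop("line ", parts$line_no[which(bad)[1]], ": locus A end precedes start")
  bad <- e$endB < e$startB
  if (any(bad)) stop("line ", parts$line_no[which(bad)[1]], ": locus B end precedes start")
  x <- pgl(e, headers = parts$headers, sorted = "unverified")
  if (strict_sorted) x <- pgl_verify_sorted(x)
  x
}

format_pgl_lines <- function(x) {
  e <- x$entries
  if (!nrow(e)) return(x$headers)
  body <- paste(e$chromA, e$startA, e$endA, e$chromB, e$startB, e$endB,
                sep = "\t")
  has_ann <- nzchar(e$annotations)
  body[has_ann] <- paste(body[has_ann], e$annotations[has_ann], sep = "\t")
  c(x$headers, body)
}

#' Write a PGL file
#'
#' Headers first, then one tab-separated line per entry (6 coordinate
#' columns plus annotations).  Round-trips byte-exactly with [read_pgl()]
#' for canonically formatted input.
#'
#' @param x a `pgl` object
#' @param dest file path, `"-"`/`NULL` for standard output, or a connection
#' @return (invisibly) the number of lines written
#' @export
write_pgl <- function(x, dest = NULL) {
  stopifnot(is_pgl(x))
  lines <- format_pgl_lines(x)
  sink <- open_sink(dest)
  if (sink$close) on.exit(close(sink$con))
  writeLines(lines, sink$con)
  invisible(length(lines))
}

#' Read a BED file
#'
#' BED3+ tab-delimited; `#` comment lines and `track`/`browser` lines are
#' skipped.  Columns 4+ are kept verbatim as annotation text.  Sortedness
#' (chrom byte-lexicographic, start, end) is detected and recorded.
#'
#' @inheritParams read_pgl
#' @return a `bed` object
#' @export
read_bed <- function(src) {
  lines <- read_source_lines(src)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !grepl("^(track|browser)([ \t]|$)", lines)
  data <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(data, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop(sprintf("line %d: BED requires at least 3 columns, found %d",
                 line_no[i], nf[i]))
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  start <- parse_coord(get(2), line_no, 2L)
  end <- parse_coord(get(3), line_no, 3L)
  bad <- end < start
  if (any(bad)) stop("line ", line_no[which(bad)[1]], ": end precedes start")
  ann <- vapply(fields, function(f) {
    if (length(f) > 3L) paste(f[-(1:3)], collapse = "\t") else ""
  }, character(1))
  r <- data.frame(chrom = get(1), start = start, end = end,
                  annotations = ann, stringsAsFactors = FALSE)
  sorted <- if (nrow(r) <= 1L || identical(bed_order(r), seq_len(nrow(r))))
    "verified" else "unsorted"
  bed(r, sorted = sorted)
}

#' Write a BED object
#'
#' @param x a `bed` object
#' @param dest file path, `"-"`/`NULL` for standard output, or a connection
#' @return (invisibly) the number of lines written
#' @export
write_bed <- function(x, dest = NULL) {
  stopifnot(is_bed(x))
  r <- x$records
  lines <- character(0)
  if (nrow(r)) {
    lines <- paste(r$chrom, r$start, r$end, sep = "\t")
    has_ann <- nzchar(r$annotations)
    lines[has_ann] <- paste(lines[has_ann], r$annotations[has_ann], sep = "\t")
  }
  sink <- open_sink(dest)
  if (sink$close) on.exit(close(sink$con))
  writeLines(lines, sink$con)
  invisible(length(lines))
}
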
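COORD_COLS <- c("chromA", "startA", "endA", "chromB", "startB", "endB")

empty_entries <- function() {
  data.frame(chromA = character(), startA = integer(), endA = integer(),
             chromB = character(), startB = integer(), endB = integer(),
             annotations = character(), stringsAsFactors = FALSE)
}

#' Construct a PGL object
#'
#' A PGL object holds paired-genomic-loci entries: two genomic anchors
#' (locus A and locus B, each chrom/start/end in 0-based half-open
#' coordinates) plus opaque annotation text (file columns 7 and beyond,
#' kept tab-joined and byte-exact).  Locus A is expected to precede locus B
#' under the entry-internal order (chromosome byte-lexicographic, then start,
#' then end); use [pgl_normalize()] to enforce this on arbitrary pairs.
#'
#' @param entries data.frame with columns `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB` and optionally `annotations` (a single
#'   character column holding the tab-joined text of columns 7+, `""` when
#'   absent).
#' @param headers character vector of header lines (each beginning with
#'   `"#"`; the prefix is added if missing).
#' @param sorted sortedness state: `"verified"` (entries known to be in file
#'   order), `"unverified"`, or `"unsorted"`.
#' @return An object of class `"pgl"`.
#' @examples
#' p <- pgl(data.frame(chromA = "chr1", startA = 100L, endA = 200L,
#'                     chromB = "chr1", startB = 500L, endB = 600L))
#' p
#' @export
pgl <- function(entries = empty_entries(), headers = character(),
                sorted = c("unverified", "verified", "unsorted")) {
  sorted <- match.arg(sorted)
  stopifnot(is.data.frame(entries))
  if (!"annotations" %in% names(entries)) entries$annotations <- rep("", nrow(entries))
  miss <- setdiff(COORD_COLS, names(entries))
  if (length(miss)) stop("missing entry columns: ", paste(miss, collapse = ", "))
  entries <- entries[, c(COORD_COLS, "annotations"), drop = FALSE]
  entries$chromA <- as.character(entries$chromA)
  entries$chromB <- as.character(entries$chromB)
  for (cl in c("startA", "endA", "startB", "endB")) {
    entries[[cl]] <- as.integer(entries[[cl]])
  }
  entries$annotations <- as.character(entries$annotations)
  validate_loci(entries$chromA, entries$startA, entries$endA)
  validate_loci(entries$chromB, entries$startB, entries$endB)
  rownames(entries) <- NULL
  if (length(headers)) {
    headers <- ifelse(startsWith(headers, "#"), headers, paste0("#", headers))
  }
  structure(list(headers = as.character(headers), entries = entries),
            sorted = sorted, class = "pgl")
}

validate_loci <- function(chrom, start, end) {
  if (any(is.na(chrom) | !nzchar(chrom))) stop("empty chromosome name")
  if (any(is.na(start) | is.na(end))) stop("NA coordinate")
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(end < start)) stop("locus end precedes start")
  invisible(TRUE)
}

#' @export
print.pgl <- function(x, n = 6L, ...) {
  cat(sprintf("PGL file: %d entries, %d header line(s), sortedness: %s\n",
              nrow(x$entries), length(x$headers), pgl_sortedness(x)))
  if (nrow(x$entries)) print(utils::head(x$entries, n))
  invisible(x)
}

#' @export
as.data.frame.pgl <- function(x, ...) x$entries

#' Number of entries in a PGL object
#' @param x a `pgl` object
#' @return integer entry count
#' @export
pgl_length <- function(x) nrow(x$entries)

#' Sortedness state of a PGL object
#' @param x a `pgl` object
#' @return `"verified"`, `"unverified"` or `"unsorted"`
#' @export
pgl_sortedness <- function(x) attr(x, "sorted")

#' Test for PGL objects
#' @param x any object
#' @export
is_pgl <- function(x) inherits(x, "pgl")

subset_pgl <- function(x, idx, sorted = "unverified") {
  pgl(x$entries[idx, , drop = FALSE], headers = x$headers, sorted = sorted)
}

#' Construct a BED object
#'
#' Single-locus records: chrom/start/end (0-based half-open) plus opaque
#' annotation text (columns 4+, tab-joined, byte-exact).
#'
#' @param records data.frame with columns `chrom`, `start`, `end` and
#'   optionally `annotations`.
#' @param sorted sortedness state as for [pgl()].
#' @return An object of class `"bed"`.
#' @export
bed <- function(records = data.frame(chrom = character(), start = integer(),
                                     end = integer(), annotations = character(),
                                     stringsAsFactors = FALSE),
                sorted = c("unverified", "verified", "unsorted")) {
  sorted <- match.arg(sorted)
  stopifnot(is.data.frame(records))
  if (!"annotations" %in% names(records)) records$annotations <- rep("", nrow(records))
  miss <- setdiff(c("chrom", "start", "end"), names(records))
  if (length(miss)) stop("missing BED columns: ", paste(miss, collapse = ", "))
  records <- records[, c("chrom", "start", "end", "annotations"), drop = FALSE]
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$annotations <- as.character(records$annotations)
  validate_loci(records$chrom, records$start, records$end)
  rownames(records) <- NULL
  structure(list(records = records), sorted = sorted, class = "bed")
}

#' @export
print.bed <- function(x, n = 6L, ...) {
  cat(sprintf("BED: %d records, sortedness: %s\n", nrow(x$records), attr(x, "sorted")))
  if (nrow(x$records)) print(utils::head(x$records, n))
  invisible(x)
}

#' @export
as.data.frame.bed <- function(x, ...) x$records

#' Test for BED objects
#' @param x any object
#' @export
is_bed <- function(x) inherits(x, "bed")

#' Parse a genomic region string
#'
#' Accepts `"chr1:100-2000"` (0-based half-open, like all package
#' coordinates) or a list/data.frame with `chrom`, `start`, `end`.
#'
#' @param region region specifier
#' @return list with `chrom`, `start`, `end`
#' @export
parse_region <- function(region) {
  if (is.list(region) && all(c("chrom", "start", "end") %in% names(region))) {
    out <- list(chrom = as.character(region$chrom)[1],
                start = as.integer(region$start)[1],
                end = as.integer(region$end)[1])
  } else if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("cannot parse region '", region,
                              "'; expected chrom:start-end")
    out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  } else {
    stop("region must be 'chrom:start-end' or a list(chrom, start, end)")
  }
  if (is.na(out$start) || is.na(out$end) || out$end < out$start || out$start < 0L)
    stop("invalid region coordinates")
  out
}

# append extra text column(s) to the tab-joined annotation field
append_ann <- function(ann, extra) {
  ifelse(nzchar(ann), paste(ann, extra, sep = "\t"), extra)
}

# number of annotation fields per entry ("" -> 0)
ann_count <- function(ann) {
  ifelse(nzchar(ann), lengths(strsplit(ann, "\t", fixed = TRUE)), 0L)
}

# extract 1-based annotation field k (file column k+6); error if absent
ann_field <- function(ann, k, what = "entry") {
  parts <- strsplit(ann, "\t", fixed = TRUE)
  vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (!nzchar(ann[i]) || length(p) < k)
      stop(sprintf("%s %d has no annotation column %d (file column %d)",
                   what, i, k, k + 6L))
    p[k]
  }, character(1))
}
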
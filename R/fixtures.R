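# Deterministic synthetic fixtures and naive reference oracles.
#
# Fixtures model the structural shape of chromatin-loop calls (two anchors
# per entry, mostly intra-chromosomal with a minority of inter-chromosomal
# contacts, free annotation columns) without any biological signal such as
# contact-distance decay.  Oracles are intentionally naive all-pairs /
# per-base enumerations with no sorting assumptions, so they cannot share
# a bug with the sweep engine.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rint <- function(n, lo, hi) {
  if (hi < lo) stop("invalid range")
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Generate a random sorted PGL fixture
#'
#' Reproducible from the seed.  Anchors are placed uniformly on the named
#' chromosomes; intra-chromosomal entries separate the two anchors by a
#' gap drawn from `span` (so the anchors themselves never overlap each
#' other), and a fraction of entries are inter-chromosomal.  Annotation
#' columns are filled with uniform scores.  Every entry satisfies the
#' A-before-B invariant and the output is sorted.
#'
#' @param n number of entries
#' @param seed RNG seed (the caller's RNG state is left untouched)
#' @param chroms named integer vector: chromosome lengths by name
#' @param anchor_size length-2 integer vector, min/max anchor width
#' @param span length-2 integer vector, min/max gap between the two
#'   anchors of an intra-chromosomal entry
#' @param inter_chrom_fraction probability that an entry is
#'   inter-chromosomal (requires >= 2 chromosomes)
#' @param n_annotation_cols number of numeric annotation columns
#' @return a sorted `pgl` object
#' @export
pgl_fixture <- function(n = 100L, seed = 1L,
                        chroms = c(chr1 = 100000L, chr2 = 100000L),
                        anchor_size = c(10L, 1000L),
                        span = c(1L, 50000L),
                        inter_chrom_fraction = 0.1,
                        n_annotation_cols = 1L) {
  stopifnot(length(chroms) >= 1L, !is.null(names(chroms)),
            anchor_size[1] <= anchor_size[2], span[1] <= span[2],
            inter_chrom_fraction >= 0, inter_chrom_fraction <= 1)
  if (2L * anchor_size[2] + span[1] > min(chroms))
    stop("anchors plus span exceed the shortest chromosome")
  if (length(chroms) < 2L && inter_chrom_fraction > 0)
    stop("inter-chromosomal entries require at least two chromosomes")
  if (n == 0L) {
    return(pgl(headers = "#chrA\tstartA\tendA\tchrB\tstartB\tendB",
               sorted = "verified"))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      inter <- stats::runif(1) < inter_chrom_fraction
      wA <- rint(1, anchor_size[1], anchor_size[2])
      wB <- rint(1, anchor_size[1], anchor_size[2])
      if (inter) {
        cs <- sample(names(chroms), 2L)
        sA <- rint(1, 0, chroms[[cs[1]]] - wA)
        sB <- rint(1, 0, chroms[[cs[2]]] - wB)
        data.frame(chromA = cs[1], startA = sA, endA = sA + wA,
                   chromB = cs[2], startB = sB, endB = sB + wB,
                   stringsAsFactors = FALSE)
      } else {
        cn <- sample(names(chroms), 1L)
        len <- chroms[[cn]]
        gap <- rint(1, span[1], min(span[2], len - wA - wB))
        sA <- rint(1, 0, len - wA - gap - wB)
        sB <- sA + wA + gap
        data.frame(chromA = cn, startA = sA, endA = sA + wA,
                   chromB = cn, startB = sB, endB = sB + wB,
                   stringsAsFactors = FALSE)
      }
    })
    e <- do.call(rbind, rows)
    if (n_annotation_cols > 0L) {
      ann <- replicate(n_annotation_cols,
                       sprintf("%.4f", stats::runif(n)), simplify = FALSE)
      e$annotations <- do.call(paste, c(ann, sep = "\t"))
    }
    pgl_sort(pgl(pgl_normalize(e),
                 headers = "#chrA\tstartA\tendA\tchrB\tstartB\tendB"))
  })
}

#' Generate a random BED fixture
#'
#' @inheritParams pgl_fixture
#' @param n number of records
#' @param size length-2 integer vector, min/max record width
#' @param named annotate records with `region_<k>` names (column 4)
#' @return a sorted `bed` object
#' @export
bed_fixture <- function(n = 50L, seed = 1L,
                        chroms = c(chr1 = 100000L, chr2 = 100000L),
                        size = c(10L, 2000L), named = TRUE) {
  with_seed(seed, {
    w <- rint(n, size[1], size[2])
    cn <- sample(names(chroms), n, replace = TRUE)
    s <- vapply(seq_len(n), function(i) rint(1, 0, chroms[[cn[i]]] - w[i]),
                numeric(1))
    r <- data.frame(chrom = cn, start = s, end = s + w,
                    annotations = if (named) paste0("region_", seq_len(n)) else "",
                    stringsAsFactors = FALSE)
    bed_sort(bed(r))
  })
}

sam_cigar_specs <- list(
  list(cigar = "100M", ref = 100L),
  list(cigar = "50M20I30M", ref = 80L),        # insertions consume no reference
  list(cigar = "10M5D85M", ref = 100L),        # deletions consume reference
  list(cigar = "5S90M5S", ref = 90L),          # clips consume no reference
  list(cigar = "40M100N40M", ref = 180L)       # skips consume reference
)

#' Generate a SAM fixture with its ground-truth PGL file
#'
#' Emits minimal SAM text (header plus paired alignment records with simple
#' CIGARs) together with the PGL file that SAM conversion must produce.
#' The expected loci are computed from the reference lengths the generator
#' itself chose when composing each CIGAR, independently of any CIGAR
#' parser.  Optionally includes an unmapped pair and a secondary alignment,
#' both of which must be ignored by the converter.
#'
#' @param n_pairs number of well-formed mapped pairs
#' @param seed RNG seed
#' @param chroms named integer vector of chromosome lengths
#' @param include_unmapped also emit one fully unmapped pair
#' @param include_secondary also emit one secondary alignment record
#' @return list with `sam` (character lines) and `expected` (sorted `pgl`)
#' @export
sam_fixture <- function(n_pairs = 10L, seed = 1L,
                        chroms = c(chr1 = 100000L, chr2 = 100000L),
                        include_unmapped = TRUE, include_secondary = TRUE) {
  with_seed(seed, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), unname(chroms)))
    aln <- character(0)
    exp_rows <- list()
    dummy <- function(qname, flag, rname, pos, cigar) {
      paste(qname, flag, rname, pos, "60", cigar, "=", "1", "0", "*", "*",
            sep = "\t")
    }
    for (k in seq_len(n_pairs)) {
      q <- sprintf("read%03d", k)
      spec1 <- sam_cigar_specs[[rint(1, 1, length(sam_cigar_specs))]]
      spec2 <- sam_cigar_specs[[rint(1, 1, length(sam_cigar_specs))]]
      c1 <- sample(names(chroms), 1)
      c2 <- sample(names(chroms), 1)
      p1 <- rint(1, 1, chroms[[c1]] - spec1$ref)
      p2 <- rint(1, 1, chroms[[c2]] - spec2$ref)
      aln <- c(aln, dummy(q, 99L, c1, p1, spec1$cigar),
               dummy(q, 147L, c2, p2, spec2$cigar))
      exp_rows[[k]] <- data.frame(
        chromA = c1, startA = p1 - 1L, endA = p1 - 1L + spec1$ref,
        chromB = c2, startB = p2 - 1L, endB = p2 - 1L + spec2$ref,
        annotations = q, stringsAsFactors = FALSE)
    }
    if (include_unmapped) {
      aln <- c(aln, dummy("unmapped01", 77L, "*", 0L, "*"),
               dummy("unmapped01", 141L, "*", 0L, "*"))
    }
    if (include_secondary) {
      aln <- c(aln, dummy("read001", 355L, names(chroms)[1], 500L, "100M"))
    }
    expected <- pgl_sort(pgl(pgl_normalize(do.call(rbind, exp_rows))))
    list(sam = c(header, aln), expected = expected)
  })
}

#' Brute-force all-pairs overlap oracle
#'
#' O(n*m) evaluation of the both-anchor overlap predicate with no sorting
#' assumptions; the reference against which the sweep engine is checked.
#'
#' @param file1,file2 `pgl` objects (any sortedness)
#' @return data.frame with integer columns `idx1`, `idx2`
#' @export
brute_overlaps <- function(file1, file2) {
  e1 <- file1$entries
  e2 <- file2$entries
  n1 <- nrow(e1); n2 <- nrow(e2)
  if (!n1 || !n2) return(data.frame(idx1 = integer(0), idx2 = integer(0)))
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  hit <- pgl_entry_overlap(e1[i, , drop = FALSE], e2[j, , drop = FALSE])
  data.frame(idx1 = i[hit], idx2 = j[hit])
}

#' Rasterize PGL entries to unit 2D base-pair cells
#'
#' Enumerates, for every entry, the set of (locus A base, locus B base)
#' unit cells covered by the rectangle locusA x locusB, as strings
#' `"chromA:a|chromB:b"`.  A guard refuses coordinates above `cap` (the
#' oracle is for small test fixtures only).
#'
#' @param x a `pgl` object or entries data.frame
#' @param cap maximum allowed coordinate
#' @return character vector: the sorted unique cell set
#' @export
pgl_rasterize <- function(x, cap = 1000L) {
  e <- if (is_pgl(x)) x$entries else x
  if (!nrow(e)) return(character(0))
  if (max(e$endA, e$endB) > cap)
    stop("rasterization refused: coordinates exceed cap of ", cap)
  cells <- lapply(seq_len(nrow(e)), function(i) {
    if (e$endA[i] == e$startA[i] || e$endB[i] == e$startB[i]) return(character(0))
    a <- seq.int(e$startA[i], e$endA[i] - 1L)
    b <- seq.int(e$startB[i], e$endB[i] - 1L)
    g <- expand.grid(a = a, b = b)
    sprintf("%s:%d|%s:%d", e$chromA[i], g$a, e$chromB[i], g$b)
  })
  sort(unique(unlist(cells)))
}

#' Rasterize BED records to unit 1D bases
#'
#' @param x a `bed` object or records data.frame
#' @param cap maximum allowed coordinate
#' @return character vector of covered bases as `"chrom:pos"`, sorted unique
#' @export
bed_rasterize <- function(x, cap = 1000L) {
  r <- if (is_bed(x)) x$records else x
  if (!nrow(r)) return(character(0))
  if (max(r$end) > cap) stop("rasterization refused: coordinates exceed cap of ", cap)
  cells <- lapply(seq_len(nrow(r)), function(i) {
    if (r$end[i] == r$start[i]) return(character(0))
    sprintf("%s:%d", r$chrom[i], seq.int(r$start[i], r$end[i] - 1L))
  })
  sort(unique(unlist(cells)))
}
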
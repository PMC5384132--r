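# Sorted-sweep overlap engine.
#
# In a sorted single-locus (BED) file, overlapping records are always
# consecutive, so a scan can stop at the first non-overlap.  In a sorted
# PGL file that holds only for locus A: consecutive entries can share
# overlapping A anchors while their B anchors interleave arbitrarily, so
# overlapping entry PAIRS need not be consecutive.  The sweep therefore
# drives on the A axis alone: for each file-1 entry it scans file 2 from a
# maintained recheck index (the first file-2 position whose locus A could
# still overlap any remaining file-1 locus A), tests the FULL 2D overlap
# (both anchors) for every candidate, and stops the scan when file 2's
# locus A start passes the current file-1 locus A end.  B-axis mismatches
# are skipped, never used to stop the scan.

# integer codes reflecting byte-lexicographic chromosome order
chrom_codes <- function(...) {
  u <- unique(c(...))
  u[order(u, method = "radix")]
}

#' Find all overlapping entry pairs between two sorted PGL files
#'
#' Returns exactly the set of index pairs (i, j) whose entries overlap at
#' both anchors, including non-sequential matches.  Both inputs must be
#' sorted (verified on entry; unsorted input raises an error rather than
#' returning silently wrong answers).
#'
#' @param file1,file2 sorted `pgl` objects
#' @return data.frame with integer columns `idx1`, `idx2`
#' @export
pgl_find_overlaps <- function(file1, file2) {
  file1 <- assert_sorted(file1, "file 1")
  file2 <- assert_sorted(file2, "file 2")
  e1 <- file1$entries
  e2 <- file2$entries
  n1 <- nrow(e1)
  n2 <- nrow(e2)
  out_i <- integer(0)
  out_j <- integer(0)
  if (n1 && n2) {
    levels <- chrom_codes(e1$chromA, e1$chromB, e2$chromA, e2$chromB)
    ca1 <- match(e1$chromA, levels); cb1 <- match(e1$chromB, levels)
    ca2 <- match(e2$chromA, levels); cb2 <- match(e2$chromB, levels)
    sa1 <- e1$startA; ea1 <- e1$endA; sb1 <- e1$startB; eb1 <- e1$endB
    sa2 <- e2$startA; ea2 <- e2$endA; sb2 <- e2$startB; eb2 <- e2$endB
    acc_i <- vector("list", n1)
    acc_j <- vector("list", n1)
    recheck <- 1L
    for (i in seq_len(n1)) {
      # advance the recheck index past file-2 entries whose locus A can
      # never overlap this or any later file-1 locus A (file 1 is sorted,
      # so later startA values only grow)
      while (recheck <= n2 &&
             (ca2[recheck] < ca1[i] ||
              (ca2[recheck] == ca1[i] && ea2[recheck] <= sa1[i]))) {
        recheck <- recheck + 1L
      }
      if (recheck > n2) break
      j <- recheck
      hits <- integer(0)
      while (j <= n2) {
        if (ca2[j] > ca1[i] || (ca2[j] == ca1[i] && sa2[j] >= ea1[i])) break
        # zero-length loci overlap nothing, hence the strict width checks
        if (ca2[j] == ca1[i] && sa2[j] < ea1[i] && sa1[i] < ea2[j] &&
            sa1[i] < ea1[i] && sa2[j] < ea2[j] &&
            cb2[j] == cb1[i] && sb2[j] < eb1[i] && sb1[i] < eb2[j] &&
            sb1[i] < eb1[i] && sb2[j] < eb2[j]) {
          hits <- c(hits, j)
        }
        j <- j + 1L
      }
      if (length(hits)) {
        acc_i[[i]] <- rep.int(i, length(hits))
        acc_j[[i]] <- hits
      }
    }
    out_i <- unlist(acc_i, use.names = FALSE)
    out_j <- unlist(acc_j, use.names = FALSE)
    if (is.null(out_i)) { out_i <- integer(0); out_j <- integer(0) }
  }
  data.frame(idx1 = out_i, idx2 = out_j)
}
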
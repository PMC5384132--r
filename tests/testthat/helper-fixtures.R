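# Shared test helpers: canonical pair keys, small-coordinate fixtures for
# the rasterization oracles, and a runner for the installed CLI.

pair_key <- function(d) sort(paste(d$idx1, d$idx2, sep = ":"))

# fixture small enough for per-base rasterization (coords <= 1000)
small_fixture <- function(n, seed, inter = 0.2) {
  pgl_fixture(n, seed = seed, chroms = c(chr1 = 1000L, chr2 = 1000L),
              anchor_size = c(5L, 40L), span = c(1L, 400L),
              inter_chrom_fraction = inter)
}

small_bed <- function(n, seed) {
  bed_fixture(n, seed = seed, chroms = c(chr1 = 1000L, chr2 = 1000L),
              size = c(5L, 60L))
}

entries_df <- function(startA, endA, startB, endB, chromA = "chr1",
                       chromB = chromA, ann = "") {
  data.frame(chromA = chromA, startA = startA, endA = endA,
             chromB = chromB, startB = startB, endB = endB,
             annotations = ann, stringsAsFactors = FALSE)
}

# the four-entry construction where non-sequential entries overlap:
# A anchors all overlap consecutively, B anchors pair 1 with 3 and 2 with 4
nonseq_pattern <- function() {
  pgl(entries_df(startA = c(100, 120, 140, 160), endA = c(200, 220, 240, 260),
                 startB = c(1000, 2000, 1050, 2050),
                 endB = c(1100, 2100, 1150, 2150)))
}

cli_exe <- function() {
  file.path(system.file(package = "pgltools"), "exec", "pgltools")
}

cli_run <- function(args, input = NULL) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(cli_exe(), args),
            stdout = TRUE, stderr = TRUE,
            input = if (is.null(input)) "" else input))
  status <- attr(out, "status")
  list(stdout = as.character(out), status = if (is.null(status)) 0L else status)
}

# stdout only, stderr discarded (for byte-identity comparisons)
cli_run_stdout <- function(args, input = NULL) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(cli_exe(), args),
            stdout = TRUE, stderr = FALSE,
            input = if (is.null(input)) "" else input))
  status <- attr(out, "status")
  list(stdout = as.character(out), status = if (is.null(status)) 0L else status)
}
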
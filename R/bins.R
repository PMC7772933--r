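#' Bin tables
#'
#' A bin table assigns each polymer bead to a genomic interval. Intervals are
#' 0-based half-open (BED convention), non-overlapping and sorted; the bead
#' `index` column is contiguous from 0.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer interval bounds in bp, 0-based half-open.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `index`.
#' @export
bin_table <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   index = seq_along(start) - 1L,
                   stringsAsFactors = FALSE)
  validate_bins(df)
  df
}

#' Build an equal-width bin table
#'
#' @param n number of beads.
#' @param resolution bin width in bp (one bead per bin).
#' @param chrom chromosome name.
#' @param start genomic start of the first bin, bp.
#' @return A bin table (see [bin_table()]).
#' @export
make_bins <- function(n, resolution = 1e6, chrom = "chrX", start = 0) {
  s <- start + (seq_len(n) - 1) * resolution
  bin_table(rep(chrom, n), s, s + resolution)
}

validate_bins <- function(bins) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bins)))
    stop_fmt("bin table must have columns %s", paste(need, collapse = ", "))
  if (any(bins$end <= bins$start))
    stop_fmt("bin table has empty or inverted intervals")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop_fmt("bins on %s are not sorted by start", ch)
    if (any(b$start[-1] < b$end[-nrow(b)]))
      stop_fmt("bins on %s overlap", ch)
  }
  invisible(bins)
}

#' Read a bin table from a BED file
#'
#' Uses the BED3(+) convention: 0-based half-open intervals.
#'
#' @param path BED file path.
#' @return A bin table.
#' @export
read_bins <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  bin_table(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L,
            GenomicRanges::end(gr))
}

#' Write a bin table as BED3
#'
#' @param bins a bin table.
#' @param path output path.
#' @export
write_bins <- function(bins, path) {
  df <- data.frame(bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

bins_as_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1L,
                                          end = bins$end))
}
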
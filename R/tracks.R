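#' Aggregate a bedGraph track onto beads
#'
#' Reads a 4-column bedGraph and collapses it to one value per bead, using
#' either the coverage-weighted mean of overlapping interval values (default)
#' or their plain sum. Only intervals on the chromosomes present in `bins`
#' are used; beads with no overlapping interval get 0.
#'
#' @param path bedGraph file.
#' @param bins bin table defining the beads.
#' @param aggregation `"mean"` (coverage-weighted) or `"sum"`.
#' @return Numeric vector of length `nrow(bins)`.
#' @export
read_bedgraph <- function(path, bins, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop_fmt("%s: malformed bedGraph (%s)", path,
                            conditionMessage(e)))
  n <- nrow(bins)
  out <- numeric(n)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% unique(bins$chrom)]
  if (length(gr) == 0) {
    message(sprintf("read %s: 0 usable intervals", path))
    return(out)
  }
  gb <- bins_as_granges(bins)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gb, gr, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(gb[q], gr[s]))
    v <- gr$score[s]
    if (aggregation == "mean") {
      num <- rowsum(w * v, q)
      den <- rowsum(w, q)
      out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
    } else {
      sv <- rowsum(v, q)
      out[as.integer(rownames(sv))] <- sv[, 1]
    }
  }
  message(sprintf("read %s: %d intervals onto %d beads", path, length(gr), n))
  out
}

#' RAP (Xist localization) time series
#'
#' Per-bead Xist localization intensities at ordered time points, floored at
#' a small positive value so intensity ratios are always defined.
#'
#' @param times numeric vector of time points in hours, strictly increasing
#'   (canonically 0, 3, 6, 24, 48).
#' @param values numeric matrix, one row per time point, one column per bead;
#'   or a list of per-time vectors.
#' @param floor_frac the floor as a fraction of the global maximum signal.
#' @return An object of class `rap_timeseries`.
#' @export
rap_timeseries <- function(times, values, floor_frac = 1e-6) {
  if (is.list(values)) values <- do.call(rbind, values)
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop_fmt("%d time points but %d signal rows", length(times), nrow(values))
  if (is.unsorted(times, strictly = TRUE))
    stop_fmt("time points must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop_fmt("RAP signals must be finite and non-negative")
  floor <- floor_frac * max(values, 1e-12)
  structure(list(times = as.numeric(times), values = pmax(values, floor),
                 floor = floor),
            class = "rap_timeseries")
}

#' @export
print.rap_timeseries <- function(x, ...) {
  cat(sprintf("RAP time series: %d beads at t = %s h (floor %.3g)\n",
              ncol(x$values), paste(x$times, collapse = ", "), x$floor))
  invisible(x)
}

#' Read RAP bedGraph tracks into a time series
#'
#' @param paths bedGraph files, one per time point, in time order.
#' @param times time points in hours matching `paths`.
#' @inheritParams read_bedgraph
#' @inheritParams rap_timeseries
#' @return A [rap_timeseries()].
#' @export
read_rap_tracks <- function(paths, times, bins, aggregation = "mean",
                            floor_frac = 1e-6) {
  if (length(paths) != length(times))
    stop_fmt("%d tracks but %d time points", length(paths), length(times))
  vals <- t(vapply(paths, read_bedgraph, numeric(nrow(bins)),
                   bins = bins, aggregation = aggregation))
  rap_timeseries(times, vals, floor_frac)
}
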
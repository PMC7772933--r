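#' Contact matrices
#'
#' A `contact_matrix` bundles a symmetric, non-negative bin-by-bin Hi-C count
#' matrix with its bin table and a per-bin "none" mask for unmappable bins.
#'
#' @param counts n x n numeric matrix, symmetric and non-negative.
#' @param bins bin table with n rows (defaults to synthetic 1 Mb bins).
#' @param mask logical vector of length n flagging unmappable ("none") bins.
#' @param unimputed optional symmetric logical matrix marking entries that
#'   remained zero after imputation (set by [impute_zeros()]).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bins = NULL, mask = NULL, unimputed = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n)
    stop_fmt("contact matrix must be square, got %d x %d", n, ncol(counts))
  if (is.null(bins)) bins <- make_bins(n)
  if (nrow(bins) != n)
    stop_fmt("bin table has %d rows for a %d-bin matrix", nrow(bins), n)
  mask <- mask %||% rep(FALSE, n)
  live <- !(mask[row(counts)] | mask[col(counts)])
  if (any(!is.finite(counts[live])))
    stop_fmt("contact matrix has non-finite entries in unmasked bins")
  if (any(counts[live] < 0))
    stop_fmt("contact matrix has negative entries")
  asym <- max(abs(counts[live] - t(counts)[live]), 0)
  tol <- 1e-9 * max(abs(counts[live]), 1)
  if (asym > tol)
    stop_fmt("contact matrix is not symmetric (max asymmetry %g)", asym)
  counts[!live] <- NA_real_
  dimnames(counts) <- NULL
  structure(list(counts = counts, bins = bins, mask = mask,
                 unimputed = unimputed),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  nz <- sum(x$counts[upper.tri(x$counts)] == 0, na.rm = TRUE)
  cat(sprintf("Hi-C contact matrix: %d bins (%s), %d masked, %d zero pairs\n",
              n, paste(unique(x$bins$chrom), collapse = ","),
              sum(x$mask), nz))
  if (!is.null(x$unimputed))
    cat(sprintf("  imputed; %d pairs remained zero\n",
                sum(x$unimputed[upper.tri(x$unimputed)])))
  invisible(x)
}

n_beads <- function(m) {
  if (inherits(m, "contact_matrix")) nrow(m$counts) else nrow(m)
}

#' Read a dense whitespace-delimited contact matrix
#'
#' `NA`/`none` tokens are allowed and flag the whole bin as unmappable.
#' The matrix must be square and symmetric to within `1e-9 * max`.
#'
#' @param path text file with a square numeric matrix.
#' @param bins optional bin table; synthetic bins are made if omitted.
#' @return A [contact_matrix()].
#' @export
read_dense_matrix <- function(path, bins = NULL) {
  m <- as.matrix(read.table(path, header = FALSE,
                            na.strings = c("NA", "na", "none", "None", "NONE"),
                            colClasses = "character"))
  suppressWarnings(storage.mode(m) <- "double")
  if (nrow(m) != ncol(m))
    stop_fmt("%s: matrix is not square (%d x %d)", path, nrow(m), ncol(m))
  # a bin is "none" when its whole row (equivalently column) is NA; any
  # remaining NA outside masked rows/columns is a format error
  mask <- unname(apply(is.na(m), 1, all) | apply(is.na(m), 2, all))
  stray <- is.na(m) & !(mask[row(m)] | mask[col(m)])
  if (any(stray))
    stop_fmt("%s: NA/none entries outside fully masked bins", path)
  if (any(m[!is.na(m)] < 0))
    stop_fmt("%s: negative contact count", path)
  live <- !(mask[row(m)] | mask[col(m)])
  asym <- max(abs(m[live] - t(m)[live]), 0)
  if (asym > 1e-9 * max(abs(m[live]), 1))
    stop_fmt("%s: matrix is asymmetric (max asymmetry %g)", path, asym)
  m2 <- m
  m2[live] <- (m[live] + t(m)[live]) / 2  # cancel sub-tolerance asymmetry
  message(sprintf("read %d x %d dense matrix from %s (%d masked bins)",
                  nrow(m), ncol(m), path, sum(mask)))
  contact_matrix(m2, bins, mask)
}

#' Read a sparse 3-column contact matrix
#'
#' Lines are `i j count`. Duplicate entries are summed; `(i,j)` and `(j,i)`
#' are merged symmetrically (again by summing).
#'
#' @param path text file with `i j count` triples.
#' @param bins bin table, or an integer giving the number of bins.
#' @param one_based set `TRUE` for 1-based bin indices (default 0-based).
#' @return A [contact_matrix()].
#' @export
read_sparse_matrix <- function(path, bins, one_based = FALSE) {
  n <- if (is.numeric(bins) && length(bins) == 1) as.integer(bins)
       else nrow(bins)
  bt <- if (is.data.frame(bins)) bins else NULL
  M <- matrix(0, n, n)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    d <- read.table(path, header = FALSE, col.names = c("i", "j", "count"))
    i <- as.integer(d$i) + if (one_based) 0L else 1L
    j <- as.integer(d$j) + if (one_based) 0L else 1L
    if (any(i < 1 | i > n | j < 1 | j > n))
      stop_fmt("%s: bin index out of range [%s,%d]", path,
               if (one_based) "1" else "0", n - !one_based)
    if (any(d$count < 0)) stop_fmt("%s: negative contact count", path)
    key <- (i - 1) * n + j
    sums <- rowsum(d$count, key)
    k <- as.numeric(rownames(sums))
    M[cbind((k - 1) %/% n + 1, (k - 1) %% n + 1)] <- sums[, 1]
  }
  S <- M + t(M)
  diag(S) <- diag(M)
  message(sprintf("read sparse matrix from %s: %d bins", path, n))
  contact_matrix(S, bt)
}

#' Write a contact or distance matrix as dense TSV
#'
#' Masked bins are written as `none`.
#'
#' @param m a [contact_matrix()] or plain matrix.
#' @param path output path.
#' @export
write_dense_matrix <- function(m, path) {
  x <- if (inherits(m, "contact_matrix")) m$counts else as.matrix(m)
  x[is.na(x)] <- NA
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) ifelse(is.na(col), "none",
                                          format(col, digits = 17)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Drop unmappable ("none") bins
#'
#' Removes masked rows/columns and returns the reduced matrix together with
#' the index map back to the original beads.
#'
#' @param m a [contact_matrix()].
#' @return A list with `matrix` (the reduced [contact_matrix()]) and
#'   `index_map`, an integer vector such that `index_map[new]` is the old
#'   (1-based) bead index.
#' @export
drop_none_bins <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  keep <- which(!m$mask)
  if (length(keep) == 0) stop_fmt("all bins are masked; nothing to keep")
  counts <- m$counts[keep, keep, drop = FALSE]
  bins <- m$bins[keep, , drop = FALSE]
  bins$index <- seq_along(keep) - 1L
  rownames(bins) <- NULL
  out <- contact_matrix(counts, bins, rep(FALSE, length(keep)),
                        if (!is.null(m$unimputed))
                          m$unimputed[keep, keep, drop = FALSE])
  list(matrix = out, index_map = keep)
}
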
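#' Convert contact counts to raw target distances
#'
#' Applies the classic polymer-physics power law `delta_ij = c_ij^(-1/3)`
#' to every positive entry. Zero entries are only tolerated if they are
#' flagged as unimputable (the `unimputed` field set by [impute_zeros()]);
#' those become a sentinel that [normalize_distances()] maps to the maximum
#' allowed distance. Any other zero entry is an error: run imputation first.
#'
#' @param m an imputed [contact_matrix()].
#' @return A numeric matrix of raw distances with `NA` sentinels for
#'   unimputable pairs, diagonal 0, and attribute `sentinel` (logical
#'   matrix).
#' @export
contacts_to_raw_distances <- function(m) {
  cm <- if (inherits(m, "contact_matrix")) m else contact_matrix(m)
  C <- cm$counts
  n <- nrow(C)
  sentinel <- cm$unimputed %||% matrix(FALSE, n, n)
  off <- !diag(n) & !is.na(C)
  bad <- off & C == 0 & !sentinel
  if (any(bad))
    stop_fmt(paste("%d zero contacts cannot be converted to target distances",
                   "(would be infinite); run impute_zeros() first"),
             sum(bad[upper.tri(bad)]))
  raw <- matrix(NA_real_, n, n)
  pos <- off & C > 0
  raw[pos] <- C[pos]^(-1 / 3)
  diag(raw) <- 0
  attr(raw, "sentinel") <- sentinel | (off & is.na(C))
  raw
}

#' Normalize raw distances to the lattice scale
#'
#' Rescales raw target distances so the largest becomes `n * sqrt(3)`, the
#' diagonal length of a cubic lattice of side `n`:
#' `delta'_ij = n * sqrt(3) * delta_ij / max(delta_ij)`. Sentinel pairs
#' (never-imputed zeros) are set to exactly `n * sqrt(3)`, the
#' least-informative consistent choice for a pair with no observed contact.
#'
#' @param raw matrix from [contacts_to_raw_distances()] (or any symmetric
#'   positive matrix with optional `NA` sentinels).
#' @param n_beads the bead count `n` setting the scale (default:
#'   `nrow(raw)`).
#' @return A `target_dist` object: list with `delta_prime`, `n_beads` and
#'   `max_allowed = n_beads * sqrt(3)`.
#' @export
normalize_distances <- function(raw, n_beads = nrow(raw)) {
  n <- nrow(raw)
  sentinel <- attr(raw, "sentinel") %||% (is.na(raw) & !diag(n))
  fin <- is.finite(raw) & !diag(n)
  if (!any(fin)) stop_fmt("no finite distances to scale")
  dmax <- max(raw[fin])
  max_allowed <- n_beads * sqrt(3)
  dp <- raw * (max_allowed / dmax)
  dp[sentinel] <- max_allowed
  diag(dp) <- 0
  attr(dp, "sentinel") <- NULL
  target_dist(dp, n_beads)
}

#' Target distance matrices
#'
#' @param delta_prime symmetric matrix of normalized target distances with
#'   zero diagonal and off-diagonal entries in `(0, n_beads * sqrt(3)]`.
#' @param n_beads bead count defining the lattice scale.
#' @param strict_max require the maximum off-diagonal entry to equal
#'   `n_beads * sqrt(3)` (true for freshly normalized matrices; kinematic
#'   intermediates may legitimately sit below the bound).
#' @return An object of class `target_dist`.
#' @export
target_dist <- function(delta_prime, n_beads = nrow(delta_prime),
                        strict_max = TRUE) {
  dp <- as.matrix(delta_prime)
  n <- nrow(dp)
  max_allowed <- n_beads * sqrt(3)
  if (any(!is.finite(dp))) stop_fmt("target distances must be finite")
  if (max(abs(dp - t(dp))) > 1e-9 * max_allowed)
    stop_fmt("target distance matrix is not symmetric")
  if (any(diag(dp) != 0)) stop_fmt("target distance diagonal must be 0")
  off <- dp[upper.tri(dp)]
  if (length(off) && (any(off <= 0) || any(off > max_allowed * (1 + 1e-9))))
    stop_fmt("off-diagonal target distances must lie in (0, n*sqrt(3)]")
  if (strict_max && length(off) &&
      abs(max(off) - max_allowed) > 1e-9 * max_allowed)
    stop_fmt("maximum target distance %g does not equal n*sqrt(3) = %g",
             max(off), max_allowed)
  dimnames(dp) <- NULL
  structure(list(delta_prime = dp, n_beads = n_beads,
                 max_allowed = max_allowed),
            class = "target_dist")
}

#' @export
print.target_dist <- function(x, ...) {
  off <- x$delta_prime[upper.tri(x$delta_prime)]
  cat(sprintf(
    "Target distances: %d beads, range [%.3f, %.3f], max allowed %.3f\n",
    nrow(x$delta_prime), min(off), max(off), x$max_allowed))
  invisible(x)
}

#' Contacts to normalized target distances in one step
#'
#' @inheritParams contacts_to_raw_distances
#' @return A [target_dist()] object.
#' @export
target_distances <- function(m) {
  normalize_distances(contacts_to_raw_distances(m))
}

#' Write / read target distance matrices
#'
#' Stored as dense TSV preceded by a header line `# n=<n> max=<n*sqrt(3)>`.
#'
#' @param targets a [target_dist()].
#' @param path file path.
#' @export
write_targets <- function(targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d max=%.17g", targets$n_beads,
                     targets$max_allowed), con)
  write.table(format(targets$delta_prime, digits = 17, trim = TRUE), con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  hdr <- readLines(path, n = 1)
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  dp <- as.matrix(read.table(path, skip = 1, header = FALSE))
  dimnames(dp) <- NULL
  target_dist(dp, n, strict_max = FALSE)
}
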
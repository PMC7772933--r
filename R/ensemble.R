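#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `coords_b` onto `coords_a`, via the standard SVD construction with
#' reflection correction (mirror images are not identified).
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with matched rows
#'   (n >= 3).
#' @param subset optional row indices to superpose on (distances and the
#'   transform still apply to all rows).
#' @return A list with `rotation` (3 x 3), `translation` (length 3),
#'   `rmsd` (over the subset) and `transformed` (all of `coords_b`
#'   transformed).
#' @export
superpose <- function(coords_a, coords_b, subset = NULL) {
  A <- coords_of(coords_a); B <- coords_of(coords_b)
  if (!all(dim(A) == dim(B))) stop_fmt("coordinate sets differ in shape")
  if (nrow(A) < 3) stop_fmt("superposition needs at least 3 points")
  subset <- subset %||% seq_len(nrow(A))
  As <- A[subset, , drop = FALSE]; Bs <- B[subset, , drop = FALSE]
  ca <- colMeans(As); cb <- colMeans(Bs)
  H <- crossprod(sweep(Bs, 2, cb), sweep(As, 2, ca))
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    warning("near-collinear coordinates; superposition is degenerate")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transformed <- sweep(sweep(B, 2, cb) %*% R, 2, ca, "+")
  rmsd <- sqrt(mean(rowSums((transformed[subset, , drop = FALSE] - As)^2)))
  list(rotation = R, translation = ca - as.vector(cb %*% R), rmsd = rmsd,
       transformed = transformed)
}

tm_d0 <- function(n) {
  d0 <- 1.24 * sign(n - 15) * abs(n - 15)^(1 / 3) - 1.8
  max(d0, 0.5)
}

#' TM-score between two bead chains
#'
#' Length-normalized structural similarity in (0, 1]: 1 for identical
#' structures, below ~0.3 for unrelated ones. Bead correspondence is fixed
#' by genomic order (no alignment search). The score is maximized over
#' superpositions by the standard iterative scheme: superpose on all beads,
#' then repeatedly re-superpose on the subset of beads closer than a
#' cutoff, over a ladder of cutoffs, keeping the best score. The
#' normalization scale is `d0 = 1.24 (n - 15)^(1/3) - 1.8`, floored at 0.5
#' (the protein convention; override via `d0`).
#'
#' @param coords_a,coords_b matched n x 3 coordinate matrices (n >= 3).
#' @param d0 normalization scale override.
#' @return The TM-score.
#' @export
tm_score <- function(coords_a, coords_b, d0 = NULL) {
  A <- coords_of(coords_a); B <- coords_of(coords_b)
  n <- nrow(A)
  if (n < 3) stop_fmt("TM-score needs at least 3 beads")
  d0 <- d0 %||% tm_d0(n)
  score_of <- function(di) mean(1 / (1 + (di / d0)^2))
  best <- 0
  for (cut in d0 * c(1, 2, 4, 8)) {
    subset <- seq_len(n)
    for (it in 1:30) {
      sp <- suppressWarnings(superpose(A, B, subset))
      di <- sqrt(rowSums((sp$transformed - A)^2))
      best <- max(best, score_of(di))
      cc <- cut
      repeat {
        nxt <- which(di < cc)
        if (length(nxt) >= 3) break
        cc <- cc * 1.5
      }
      if (length(nxt) == length(subset) && all(nxt == subset)) break
      subset <- nxt
    }
  }
  best
}

#' Q-scores of an ensemble
#'
#' The Q-score of a structure is its mean pairwise TM-score against every
#' other member of the pool; the top-ranked structures are taken as the
#' representative models.
#'
#' @param members a list of structures (any structure-bearing object (coordinate matrix, `structure3d`, conformation or fit)), or
#'   a precomputed symmetric TM-score matrix.
#' @return Numeric vector of per-member Q-scores.
#' @export
q_score <- function(members) {
  tm <- if (is.matrix(members)) members else tm_matrix(members)
  k <- nrow(tm)
  if (k < 2) stop_fmt("Q-score needs at least 2 ensemble members")
  (rowSums(tm) - diag(tm)) / (k - 1)
}

tm_matrix <- function(members) {
  k <- length(members)
  tm <- diag(1, k)
  if (k >= 2)
    for (i in 1:(k - 1))
      for (j in (i + 1):k)
        tm[i, j] <- tm[j, i] <- tm_score(members[[i]], members[[j]])
  tm
}

#' Run an ensemble of independent reconstructions
#'
#' Repeats initialization + annealing once per seed (the reference protocol
#' uses 40 independent jobs), scores all members by Q-score, and ranks them
#' (descending Q, ties broken by lower final loss, then seed order).
#'
#' @param targets a [target_dist()].
#' @param n_runs number of independent fits (>= 2).
#' @param seeds distinct integer seeds, one per run (default
#'   `seq_len(n_runs)`).
#' @param schedule an [anneal_schedule()].
#' @return An object of class `structure_ensemble`: list with `members`
#'   (the `lattice_fit`s), `tm` (pairwise TM-scores), `q_scores`, `order`
#'   (ranking) and `seeds`.
#' @export
run_ensemble <- function(targets, n_runs = 40, seeds = NULL,
                         schedule = anneal_schedule()) {
  if (n_runs < 2) stop_fmt("an ensemble needs at least 2 runs")
  seeds <- seeds %||% seq_len(n_runs)
  if (anyDuplicated(seeds)) stop_fmt("seeds must be distinct")
  if (length(seeds) != n_runs)
    stop_fmt("%d seeds for %d runs", length(seeds), n_runs)
  members <- lapply(seeds, function(s) {
    set.seed(s)
    fit_structure(targets, schedule = schedule)
  })
  tm <- tm_matrix(members)
  q <- q_score(tm)
  loss <- vapply(members, function(f) f$loss_final, numeric(1))
  ord <- order(-q, loss, seq_along(members))
  structure(list(members = members, tm = tm, q_scores = q, order = ord,
                 seeds = seeds),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf(
    "Structure ensemble: %d members, Q-scores in [%.3f, %.3f]\n",
    length(x$members), min(x$q_scores), max(x$q_scores)))
  cat(sprintf("  top member: seed %d (Q = %.3f)\n", x$seeds[x$order[1]],
              x$q_scores[x$order[1]]))
  invisible(x)
}

#' Top-ranked ensemble members
#'
#' @param ensemble a [run_ensemble()] result.
#' @param k how many members.
#' @return The `k` best `lattice_fit`s by Q-score ranking.
#' @export
top_structures <- function(ensemble, k = 3) {
  ensemble$members[head(ensemble$order, k)]
}

#' Pearson correlation between realized and target distances
#'
#' Correlates the upper-triangle entries of the structure's Euclidean
#' distance matrix with the target-distance matrix; the p-value is the
#' standard t-test of [stats::cor.test()].
#'
#' @param structure any structure-bearing object (coordinate matrix, `structure3d`, conformation or fit).
#' @param targets a [target_dist()] or distance matrix.
#' @return A list with `r` and `p_value`.
#' @export
distance_correlation <- function(structure, targets) {
  xyz <- coords_of(structure)
  dp <- delta_of(targets)
  if (nrow(xyz) != nrow(dp))
    stop_fmt("structure has %d beads but targets %d", nrow(xyz), nrow(dp))
  d <- as.matrix(dist(xyz))
  x <- d[upper.tri(d)]
  y <- dp[upper.tri(dp)]
  if (sd(x) == 0 || sd(y) == 0)
    stop_fmt("correlation undefined: constant distance vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
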
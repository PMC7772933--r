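#' Synthetic ground-truth structures
#'
#' Generates lattice-valid bead chains for end-to-end testing without any
#' external data:
#' * `"helix"` — a lattice-snapped helix (monotone along z), repaired to
#'   satisfy all chain constraints;
#' * `"random_walk_lattice"` — a plain self-avoiding chain from
#'   [init_chain()];
#' * `"two_domain"` — two compact spherical domains joined by a short
#'   linker, mimicking the bipartite geometry of the inactive X.
#'
#' Uses R's RNG; call [set.seed()] for deterministic output.
#'
#' @param n_beads chain length.
#' @param shape one of `"two_domain"`, `"helix"`, `"random_walk_lattice"`.
#' @param resolution bin width in bp for the attached bin table.
#' @param chrom chromosome name for the bin table.
#' @return A [lattice_conformation()] with attribute `bins`; for
#'   `"two_domain"` also attribute `domains` (per-bead domain labels).
#' @export
make_ground_truth <- function(n_beads,
                              shape = c("two_domain", "helix",
                                        "random_walk_lattice"),
                              resolution = 1e6, chrom = "chrX") {
  shape <- match.arg(shape)
  n <- as.integer(n_beads)
  side <- 5L * n
  conf <- switch(shape,
    random_walk_lattice = init_chain(n),
    helix = {
      theta <- (seq_len(n) - 1) * 0.5
      raw <- cbind(side / 2 + 4.5 * cos(theta),
                   side / 2 + 4.5 * sin(theta),
                   side / 4 + (seq_len(n) - 1) * 0.9)
      snapped <- round(raw)
      storage.mode(snapped) <- "integer"
      rep <- cpp_repair_chain(snapped, side, 100L)
      if (!rep$valid)
        stop_fmt("helix could not be repaired onto the lattice")
      lattice_conformation(rep$coords, side)
    },
    two_domain = {
      rho <- max(3, ceiling((n / 2)^(1 / 3)) + 2)
      D <- 5 * rho
      n_link <- max(4L, as.integer(ceiling((D - 2 * rho) / 2)) + 2L)
      n1 <- (n - n_link) %/% 2L
      n2 <- n - n_link - n1
      if (n1 < 2) stop_fmt("two_domain needs more beads (n >= %d)",
                           2 * (2 + n_link))
      ctrA <- c(side / 2 - D / 2, side / 2, side / 2)
      ctrB <- ctrA + c(D, 0, 0)
      frac <- seq_len(n_link) / (n_link + 1)
      centers <- rbind(
        matrix(ctrA, n1, 3, byrow = TRUE),
        t(vapply(frac, function(f) ctrA + f * (ctrB - ctrA), numeric(3))),
        matrix(ctrB, n2, 3, byrow = TRUE))
      radius <- c(rep(rho, n1), rep(3, n_link), rep(rho, n2))
      conf <- init_chain(n, centers = centers, radius = radius,
                         backtrack = 5, restarts = 200)
      attr(conf, "domains") <- rep(c("A", "linker", "B"),
                                   c(n1, n_link, n2))
      conf
    })
  attr(conf, "bins") <- make_bins(n, resolution, chrom)
  conf
}

#' Contacts from a known structure
#'
#' Inverts the contact-to-distance power law: `c_ij = (d_ij / scale)^(-3)`,
#' so that [contacts_to_raw_distances()] recovers `d_ij / scale` exactly —
#' a deterministic round-trip oracle. A chosen fraction of off-diagonal
#' pairs is then zeroed symmetrically (uniformly at random) to exercise
#' imputation; optionally Poisson noise replaces the deterministic counts.
#'
#' @param structure any structure-bearing object (coordinate matrix, `structure3d`, conformation or fit).
#' @param scale distance scale of the power law.
#' @param zero_fraction fraction of bead pairs set to zero, in `[0, 1)`.
#' @param poisson draw counts as `rpois(lambda = c_ij)` for noise-robustness
#'   tests (breaks the exact round-trip).
#' @param bins optional bin table for the result.
#' @return A [contact_matrix()].
#' @export
structure_to_contacts <- function(structure, scale = 1, zero_fraction = 0,
                                  poisson = FALSE, bins = NULL) {
  xyz <- coords_of(structure)
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  if (any(d[upper.tri(d)] == 0))
    stop_fmt("structure has coincident beads; distances of 0 cannot be "
             %+% "converted to contacts")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop_fmt("zero_fraction must be in [0, 1)")
  C <- (d / scale)^(-3)
  diag(C) <- 0
  if (poisson) {
    up <- upper.tri(C)
    C[up] <- rpois(sum(up), C[up])
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
  }
  if (zero_fraction > 0) {
    pairs <- which(upper.tri(C), arr.ind = TRUE)
    nz <- floor(zero_fraction * nrow(pairs))
    hit <- pairs[sample.int(nrow(pairs), nz), , drop = FALSE]
    C[hit] <- 0
    C[hit[, c(2, 1), drop = FALSE]] <- 0
  }
  bins <- bins %||% attr(structure, "bins") %||% make_bins(n)
  contact_matrix(C, bins)
}

`%+%` <- function(a, b) paste0(a, b)

#' Synthetic Xist RAP time series
#'
#' Emulates the qualitative shape of Xist localization during XCI: at every
#' time point the signal peaks at the Xist locus and decays exponentially
#' with genomic distance; the spread width grows with time while the
#' amplitude rises through 24 h and drops by 48 h (the locus signal falls
#' late in XCI). Small positive noise is added and values are floored.
#'
#' @param n_beads number of beads.
#' @param xist_bead 1-based bead carrying the Xist locus.
#' @param times time points in hours.
#' @param spread_rate growth of the spread width per hour (beads/h).
#' @param lambda0 spread width at time 0 (beads).
#' @param noise_sd relative amplitude of the additive noise.
#' @return A [rap_timeseries()].
#' @export
make_rap_timeseries <- function(n_beads, xist_bead, times = c(0, 3, 6, 24, 48),
                                spread_rate = 0.5, lambda0 = 3,
                                noise_sd = 0.02) {
  if (xist_bead < 1 || xist_bead > n_beads)
    stop_fmt("xist_bead must be in [1, %d]", n_beads)
  amp <- function(t) ifelse(t <= 24, 1 + 2 * t / 24,
                            3 - 0.8 * (t - 24) / 24)
  i <- seq_len(n_beads)
  vals <- t(vapply(times, function(t) {
    lam <- lambda0 + spread_rate * t
    a <- amp(t)
    a * exp(-abs(i - xist_bead) / lam) +
      abs(rnorm(n_beads, 0, noise_sd * a))
  }, numeric(n_beads)))
  rap_timeseries(times, vals)
}

#' One-call synthetic fixture
#'
#' Ground-truth structure, consistent contact matrix (with zeroed pairs)
#' and normalized target distances, plus a RAP series — everything the
#' pipeline needs, generated in memory.
#'
#' @inheritParams make_ground_truth
#' @inheritParams structure_to_contacts
#' @param xist_bead Xist locus bead for the RAP series.
#' @return A list with `truth`, `contacts`, `imputed`, `targets`, `rap`
#'   and `bins`.
#' @export
simulate_fixture <- function(n_beads = 50, shape = "two_domain",
                             zero_fraction = 0.2, resolution = 1e6,
                             xist_bead = ceiling(n_beads / 2)) {
  truth <- make_ground_truth(n_beads, shape, resolution)
  contacts <- structure_to_contacts(truth, zero_fraction = zero_fraction)
  imputed <- impute_zeros(contacts)
  targets <- target_distances(imputed)
  rap <- make_rap_timeseries(n_beads, xist_bead)
  list(truth = truth, contacts = contacts, imputed = imputed,
       targets = targets, rap = rap, bins = attr(truth, "bins"))
}
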
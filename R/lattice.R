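#' Cubic-lattice chain conformations
#'
#' A `lattice_conformation` is an n x 3 integer matrix of bead positions on
#' a cubic lattice of side `s = 5 n`, satisfying the chain constraints (all
#' in squared lattice distances): consecutive beads at `{2..10} \ {8}`, and
#' every other pair at `>= 2` and `!= 8` (excluded volume / anti-knotting).
#'
#' @param coords n x 3 integer matrix.
#' @param side lattice side (default `5 * nrow(coords)`).
#' @param validate run the full constraint audit.
#' @return An object of class `lattice_conformation`.
#' @export
lattice_conformation <- function(coords, side = 5L * nrow(coords),
                                 validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 3) stop_fmt("coordinates must be n x 3")
  obj <- structure(coords, side = as.integer(side),
                   class = "lattice_conformation")
  if (validate) {
    a <- audit_conformation(obj)
    if (!a$valid)
      stop_fmt("invalid conformation: %d violations (first: %s)",
               a$n_violations, a$messages[1])
  }
  obj
}

unclass_coords <- function(conf) {
  x <- unclass(conf)
  attr(x, "side") <- NULL
  x
}

lattice_side <- function(conf) attr(conf, "side")

#' @export
print.lattice_conformation <- function(x, ...) {
  cat(sprintf("Lattice conformation: %d beads on a %d^3 lattice\n",
              nrow(x), lattice_side(x)))
  invisible(x)
}

#' Lattice volume
#'
#' The simulation lattice has side `s = 5 n`, so volume `(5 n)^3` — large
#' enough that boundary effects are negligible.
#'
#' @param n_beads chain length, at least 2.
#' @return The number of lattice sites `(5 n)^3`.
#' @export
lattice_volume <- function(n_beads) {
  if (n_beads < 2) stop_fmt("a chain needs at least 2 beads")
  (5 * n_beads)^3
}

#' Bond and excluded-volume predicates
#'
#' `bond_valid()` tests the bonded (consecutive-bead) constraint: squared
#' Euclidean distance in `{2..10}` excluding 8. `excluded_volume_valid()`
#' tests a candidate site against all beads of a conformation (optionally
#' skipping some): squared distance `>= 2` and `!= 8` to each.
#'
#' @param site_a,site_b,site integer coordinate triples.
#' @param conformation a [lattice_conformation()] or integer matrix.
#' @param skip_indices bead indices (1-based) to exclude from the check.
#' @return Logical.
#' @export
bond_valid <- function(site_a, site_b) {
  d2 <- sum((as.numeric(site_a) - as.numeric(site_b))^2)
  d2 >= 2 && d2 <= 10 && d2 != 8
}

#' @rdname bond_valid
#' @export
excluded_volume_valid <- function(site, conformation,
                                  skip_indices = integer(0)) {
  xyz <- coords_of(conformation)
  if (length(skip_indices)) xyz <- xyz[-skip_indices, , drop = FALSE]
  if (nrow(xyz) == 0) return(TRUE)
  d2 <- colSums((t(xyz) - as.numeric(site))^2)
  all(d2 >= 2 & d2 != 8)
}

#' Initialize a self-avoiding chain on the lattice
#'
#' Sequential growth: the first bead is placed uniformly at random; each
#' subsequent bead is drawn uniformly from the sites that satisfy the bond
#' constraint with its predecessor and excluded volume with all earlier
#' beads. Dead ends trigger backtracking (drop the last `backtrack` beads
#' and regrow); persistent failure restarts from scratch, up to `restarts`
#' times.
#'
#' @param n_beads chain length (>= 2).
#' @param centers optional n x 3 matrix of per-bead domain centres.
#' @param radius optional length-n vector of domain radii (`Inf` = free);
#'   used with `centers` to bias growth into prescribed regions.
#' @param backtrack beads removed on a dead end.
#' @param restarts restarts allowed before giving up.
#' @return A [lattice_conformation()]. Uses R's RNG; call [set.seed()] for
#'   reproducibility.
#' @export
init_chain <- function(n_beads, centers = NULL, radius = NULL,
                       backtrack = 10, restarts = 50) {
  if (n_beads < 2) stop_fmt("a chain needs at least 2 beads")
  side <- 5L * as.integer(n_beads)
  if (!is.null(centers) && is.null(radius))
    stop_fmt("centers given without radius")
  xyz <- cpp_init_chain(as.integer(n_beads), side, centers, radius,
                        as.integer(backtrack), as.integer(restarts))
  lattice_conformation(xyz, side, validate = FALSE)
}

#' Propose a single-bead move
#'
#' Picks a uniformly random bead and a uniformly random site from its
#' 26-site Moore neighbourhood. The proposal is `valid` only if the new
#' site is in bounds, keeps the bond constraint with sequential neighbours
#' and excluded volume with every other bead; otherwise it counts as a
#' rejected trial.
#'
#' @param conformation a [lattice_conformation()].
#' @return A list with `bead` (1-based), `old_site`, `new_site`, `valid`.
#' @export
propose_move <- function(conformation) {
  cpp_propose_move(unclass_coords(conformation), lattice_side(conformation))
}

#' Apply a (valid) move proposal
#'
#' @param conformation a [lattice_conformation()].
#' @param proposal a proposal from [propose_move()] with `valid = TRUE`.
#' @return The updated conformation.
#' @export
apply_move <- function(conformation, proposal) {
  if (!isTRUE(proposal$valid)) stop_fmt("cannot apply an invalid proposal")
  conformation[proposal$bead, ] <- proposal$new_site
  conformation
}

#' Apply constraint-valid random moves
#'
#' Repeatedly proposes single-bead Moore moves and applies every one that
#' satisfies the chain constraints (no energy criterion) — useful for
#' stress-testing the constraint machinery.
#'
#' @param conformation a [lattice_conformation()].
#' @param n_moves number of applied (not proposed) moves.
#' @return The updated conformation, with attributes `applied` and `trials`.
#' @export
random_moves <- function(conformation, n_moves) {
  res <- cpp_random_moves(unclass_coords(conformation),
                          lattice_side(conformation), as.integer(n_moves))
  out <- lattice_conformation(res$coords, lattice_side(conformation),
                              validate = FALSE)
  attr(out, "applied") <- res$applied
  attr(out, "trials") <- res$trials
  out
}

#' Full O(n^2) constraint audit
#'
#' Checks bounds, every bonded pair against `{2..10} \ {8}` and every
#' non-bonded pair against `>= 2, != 8` (squared lattice distances).
#'
#' @param conformation a [lattice_conformation()] or integer matrix.
#' @param side lattice side if `conformation` is a plain matrix.
#' @return A list with `valid`, `n_violations` and up to 20 `messages`.
#' @export
audit_conformation <- function(conformation,
                               side = attr(conformation, "side")) {
  xyz <- coords_of(conformation)
  storage.mode(xyz) <- "integer"
  res <- cpp_audit(xyz, as.integer(side %||% (5L * nrow(xyz))))
  list(valid = res$n_violations == 0, n_violations = res$n_violations,
       messages = res$messages)
}
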
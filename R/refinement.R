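#' Insert beads for hierarchical resolution refinement
#'
#' Raises the resolution of a fitted coarse chain by a factor `k`: the
#' coarse beads keep their relative geometry (coordinates are uniformly
#' scaled by `k` and recentred in the larger lattice of side
#' `5 * n_fine`), and `k - 1` beads are laid into every coarse gap by
#' growing them toward the straight-line interpolation between the flanking
#' coarse beads, under the same bond/excluded-volume constraints as chain
#' initialization.
#'
#' The literal insertion rule yields `n + (k-1)(n-1)` beads, not `k n`:
#' the trailing `k - 1` fine bins of the last coarse bin have no bead.
#' `pad_terminal = TRUE` appends them so the chain reaches `k n` beads.
#'
#' @param conformation the coarse [lattice_conformation()].
#' @param factor integer resolution factor `k >= 2` (10 turns 400 kb into
#'   40 kb).
#' @param pad_terminal grow `k - 1` trailing beads after the last coarse
#'   bead.
#' @param attempts placement retries per gap before giving up.
#' @return A [lattice_conformation()] with attribute `coarse_index` giving
#'   the fine-chain positions of the original beads.
#' @export
insert_beads <- function(conformation, factor, pad_terminal = FALSE,
                         attempts = 500) {
  k <- as.integer(factor)
  if (k < 2) stop_fmt("refinement factor must be >= 2")
  xyz <- coords_of(conformation)
  n <- nrow(xyz)
  n_fine <- n + (k - 1L) * (n - 1L) + if (pad_terminal) k - 1L else 0L
  side <- 5L * n_fine
  scaled <- xyz * k
  # recentre the scaled chain in the fine lattice (translation preserves
  # all pairwise distance ratios exactly)
  for (d in 1:3) {
    lo <- min(scaled[, d]); hi <- max(scaled[, d])
    if (hi - lo >= side)
      stop_fmt("scaled chain does not fit the fine lattice")
    scaled[, d] <- scaled[, d] - lo + (side - 1L - (hi - lo)) %/% 2L
  }
  storage.mode(scaled) <- "integer"
  # a committed early gap can occasionally wall off a later corridor;
  # restarting the whole insertion re-randomizes the committed beads
  fine <- NULL
  for (restart in 1:30) {
    fine <- tryCatch(cpp_insert_beads(scaled, k, side, as.integer(attempts)),
                     error = function(e) e)
    if (!inherits(fine, "error")) break
  }
  if (inherits(fine, "error"))
    stop_fmt("bead insertion failed after 30 restarts (%s)",
             conditionMessage(fine))
  if (pad_terminal) {
    for (i in seq_len(k - 1L)) fine <- rbind(fine, grow_one_bead(fine, side))
  }
  out <- lattice_conformation(fine, side, validate = FALSE)
  attr(out, "coarse_index") <- seq(1L, by = k, length.out = n)
  out
}

# append one bead bond-valid to the chain end, EV-valid to all others
grow_one_bead <- function(xyz, side) {
  prev <- xyz[nrow(xyz), ]
  off <- bond_offset_table()
  cand <- sweep(off, 2, prev, "+")
  ok <- apply(cand, 1, function(s) {
    all(s >= 0) && all(s < side) &&
      excluded_volume_valid(s, xyz, skip_indices = nrow(xyz)) &&
      bond_valid(s, prev)
  })
  if (!any(ok)) stop_fmt("cannot grow terminal bead")
  cand[sample(which(ok), 1), ]
}

bond_offset_table <- function() {
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  d2 <- rowSums(g^2)
  g[d2 >= 2 & d2 <= 10 & d2 != 8, , drop = FALSE]
}

#' Build the fine-resolution bin table for a refined chain
#'
#' Each coarse bead maps to the first fine bin of its window; consecutive
#' inserted beads map to the following fine bins. With the literal
#' insertion rule the residual `k - 1` terminal bins are unrepresented
#' unless the chain was padded.
#'
#' @param bins coarse bin table.
#' @param factor resolution factor `k`.
#' @param n_fine number of beads in the refined chain.
#' @return A fine bin table with `n_fine` rows.
#' @export
make_fine_bins <- function(bins, factor, n_fine) {
  res <- (bins$end[1] - bins$start[1]) / factor
  start0 <- bins$start[1]
  s <- start0 + (seq_len(n_fine) - 1) * res
  bin_table(rep(bins$chrom[1], n_fine), s, s + res)
}

#' Refine a structure at low fixed starting temperature
#'
#' Runs the annealer on an already-inserted fine chain with starting
#' temperature 0.1 and a per-temperature trial budget of `trials_factor *
#' n_fine` (replacing the usual `100 n` cap); cooling rate and the
#' quota/stop rules are unchanged. Because the 10-per-bead acceptance quota
#' cannot be met within `5 n` trials, this amounts to `stop_after_failed`
#' short sweeps of local refinement — the coarse geometry is preserved and
#' only polished.
#'
#' @param conformation the fine [lattice_conformation()] from
#'   [insert_beads()].
#' @param targets_fine a [target_dist()] at the fine resolution.
#' @param t_start starting temperature.
#' @param trials_factor per-temperature trial budget, times `n_fine`.
#' @param schedule base [anneal_schedule()] supplying the remaining knobs.
#' @return A `lattice_fit` (see [fit_structure()]).
#' @export
refine_structure <- function(conformation, targets_fine, t_start = 0.1,
                             trials_factor = 5,
                             schedule = anneal_schedule()) {
  n_fine <- nrow(conformation)
  dp <- delta_of(targets_fine)
  if (nrow(dp) != n_fine)
    stop_fmt("fine targets have %d beads but chain has %d", nrow(dp), n_fine)
  sch <- schedule
  sch$t0 <- t_start
  fit_structure(targets_fine, schedule = sch, conformation = conformation,
                trial_cap = trials_factor * n_fine)
}
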
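#' Annealing schedules
#'
#' Bundles the simulated-annealing control parameters: geometric cooling
#' `T_c = t0 * rate^c` from `t0 = 10`, a per-temperature quota of 10
#' accepted moves per bead, a per-temperature trial cap of `100 n`, a halt
#' after 3 consecutive temperatures missing the quota, and the loss weight
#' `w = 1e-4`.
#'
#' @param t0 initial temperature.
#' @param rate cooling factor in (0, 1).
#' @param quota_per_bead accepted moves per bead required at each
#'   temperature.
#' @param trial_cap_factor per-temperature trial cap, times `n`.
#' @param stop_after_failed consecutive quota failures that halt annealing.
#' @param w loss weight.
#' @param max_temps hard safety cap on the number of temperature steps.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = 10, rate = 0.9, quota_per_bead = 10,
                            trial_cap_factor = 100, stop_after_failed = 3,
                            w = 1e-4, max_temps = 5000) {
  if (t0 <= 0) stop_fmt("t0 must be positive")
  if (rate <= 0 || rate >= 1) stop_fmt("rate must be in (0, 1)")
  if (quota_per_bead < 1 || trial_cap_factor < 1 || stop_after_failed < 1)
    stop_fmt("quota, cap factor and failure count must be >= 1")
  structure(list(t0 = t0, rate = rate, quota_per_bead = quota_per_bead,
                 trial_cap_factor = trial_cap_factor,
                 stop_after_failed = stop_after_failed, w = w,
                 max_temps = max_temps),
            class = "anneal_schedule")
}

#' Cooling schedule temperature
#'
#' @param c number of completed temperature decrements (0 = start).
#' @param schedule an [anneal_schedule()].
#' @return `t0 * rate^c`.
#' @export
annealing_temperature <- function(c, schedule = anneal_schedule()) {
  if (any(c < 0)) stop_fmt("decrement count must be >= 0")
  schedule$t0 * schedule$rate^c
}

delta_of <- function(targets) {
  if (inherits(targets, "target_dist")) targets$delta_prime
  else as.matrix(targets)
}

#' Loss against target distances
#'
#' `L = sum_{i<j} w (d_ij - delta'_ij)^2 / delta'_ij^2`, with `d_ij` the
#' realized Euclidean distance in the conformation. The squared target in
#' the denominator normalizes extremely large or small targets.
#'
#' @param conformation a [lattice_conformation()] (or coordinate matrix).
#' @param targets a [target_dist()] (or matrix of normalized distances).
#' @param w loss weight.
#' @return Non-negative scalar loss.
#' @export
chain_loss <- function(conformation, targets, w = 1e-4) {
  xyz <- coords_of(conformation)
  dp <- delta_of(targets)
  if (nrow(xyz) != nrow(dp))
    stop_fmt("conformation has %d beads but targets %d", nrow(xyz), nrow(dp))
  if (any(dp[upper.tri(dp)] <= 0))
    stop_fmt("target distances must be positive off the diagonal")
  storage.mode(xyz) <- "integer"
  cpp_loss(xyz, dp, w)
}

#' Incremental loss change for a move
#'
#' `delta E = L(new) - L(old)` computed in O(n) from the terms involving
#' the moved bead only.
#'
#' @inheritParams chain_loss
#' @param proposal a proposal from [propose_move()].
#' @return The scalar loss change.
#' @export
delta_loss <- function(conformation, targets, proposal, w = 1e-4) {
  xyz <- coords_of(conformation)
  storage.mode(xyz) <- "integer"
  cpp_pair_delta_loss(xyz, delta_of(targets), as.integer(proposal$bead),
                      as.integer(proposal$new_site), w)
}

#' Metropolis-Hastings acceptance
#'
#' Moves that lower the loss (`delta_e < 0`) are always accepted; uphill
#' moves are accepted with probability `exp(-delta_e / temperature)`.
#' Vectorized over `delta_e`; consumes R's RNG stream.
#'
#' @param delta_e loss change(s).
#' @param temperature current temperature (> 0).
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (temperature <= 0) stop_fmt("temperature must be positive")
  ifelse(delta_e < 0, TRUE,
         runif(length(delta_e)) < exp(-delta_e / temperature))
}

#' Fit a 3D chromosome structure by simulated annealing
#'
#' The central model fit: starting from a random (or supplied)
#' self-avoiding chain, single-bead Moore moves are proposed and accepted
#' by the Metropolis rule against the target-distance loss, under geometric
#' cooling. At each temperature, trials run until `quota_per_bead * n`
#' acceptances or `trial_cap_factor * n` trials; the process halts after
#' `stop_after_failed` consecutive temperatures missing the quota.
#' Constraint-violating proposals count as trials but never as acceptances.
#'
#' Uses R's RNG; call [set.seed()] first for a reproducible fit.
#'
#' @param targets a [target_dist()] object (or matrix of normalized target
#'   distances).
#' @param schedule an [anneal_schedule()].
#' @param conformation optional starting [lattice_conformation()]; a fresh
#'   chain is grown if omitted.
#' @param trial_cap optional absolute per-temperature trial cap, overriding
#'   `trial_cap_factor * n` (used by [refine_structure()]).
#' @return An object of class `lattice_fit` with components `conformation`,
#'   `targets`, `trace` (one row per temperature), `loss_initial`,
#'   `loss_final` and `schedule`.
#' @seealso [distance_correlation()],
#'   [run_ensemble()]
#' @export
fit_structure <- function(targets, schedule = anneal_schedule(),
                          conformation = NULL, trial_cap = NULL) {
  if (!inherits(targets, "target_dist"))
    targets <- target_dist(as.matrix(targets), strict_max = FALSE)
  n <- nrow(targets$delta_prime)
  if (is.null(conformation)) conformation <- init_chain(n)
  if (nrow(conformation) != n)
    stop_fmt("conformation has %d beads but targets %d",
             nrow(conformation), n)
  side <- lattice_side(conformation)
  res <- cpp_anneal(unclass_coords(conformation), side,
                    targets$delta_prime, schedule$w, schedule$t0,
                    schedule$rate, as.integer(schedule$quota_per_bead * n),
                    as.numeric(trial_cap %||%
                               (schedule$trial_cap_factor * n)),
                    as.integer(schedule$stop_after_failed),
                    as.integer(schedule$max_temps))
  trace <- as.data.frame(res$trace)
  names(trace) <- c("temperature", "trials", "accepted", "loss", "loss_min")
  structure(list(conformation = lattice_conformation(res$coords, side,
                                                     validate = FALSE),
                 targets = targets, trace = trace,
                 loss_initial = res$loss_initial,
                 loss_final = res$loss_final,
                 schedule = schedule, call = match.call()),
            class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf(
    "Lattice structure fit: %d beads, %d temperatures\n  loss %.4g -> %.4g\n",
    nrow(x$conformation), nrow(x$trace), x$loss_initial, x$loss_final))
  invisible(x)
}

#' @export
summary.lattice_fit <- function(object, ...) {
  dc <- distance_correlation(object, object$targets)
  out <- list(n_beads = nrow(object$conformation),
              n_temperatures = nrow(object$trace),
              temperature_range = range(object$trace$temperature),
              loss_initial = object$loss_initial,
              loss_final = object$loss_final,
              pearson_r = dc$r, pearson_p = dc$p_value)
  class(out) <- "summary.lattice_fit"
  out
}

#' @export
print.summary.lattice_fit <- function(x, ...) {
  cat(sprintf("Lattice structure fit of %d beads\n", x$n_beads))
  cat(sprintf("  %d temperatures, T in [%.3g, %.3g]\n", x$n_temperatures,
              x$temperature_range[1], x$temperature_range[2]))
  cat(sprintf("  loss: %.6g -> %.6g (%.1f%% of initial)\n", x$loss_initial,
              x$loss_final, 100 * x$loss_final / x$loss_initial))
  cat(sprintf("  target vs realized distance Pearson r = %.3f (p = %.2g)\n",
              x$pearson_r, x$pearson_p))
  invisible(x)
}

#' @export
coef.lattice_fit <- function(object, ...) {
  unclass_coords(object$conformation)
}

#' @export
fitted.lattice_fit <- function(object, ...) {
  as.matrix(dist(unclass_coords(object$conformation)))
}

#' @export
residuals.lattice_fit <- function(object, ...) {
  fitted(object) - object$targets$delta_prime
}

#' @export
plot.lattice_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(seq_len(nrow(x$trace)) - 1, x$trace$loss, type = "l", log = "y",
       xlab = "temperature step", ylab = "loss",
       main = "annealing trajectory", ...)
  xyz <- unclass_coords(x$conformation)
  plot(xyz[, 1], xyz[, 2], type = "o", pch = 16, cex = 0.5,
       xlab = "x", ylab = "y", main = "chain (xy projection)")
  invisible(x)
}
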
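dt_grid <- diff(c(0, 3, 6, 24, 48))

test_that("pairwise RAP intensity is the arithmetic mean", {
  expect_equal(pair_rap(c(2, 4), 1, 2), 3)
  expect_equal(pair_rap(c(7, 7, 7), 2, 3), 7)
  eps <- 1e-6
  expect_equal(pair_rap(c(eps, eps), 1, 2), eps)
})

test_that("constant RAP reduces the velocity model to linear interpolation", {
  n <- 8
  D0 <- rand_symmetric(n, 8, 12)
  D48 <- rand_symmetric(n, 1, 4)
  rap <- rap_timeseries(c(0, 3, 6, 24, 48), matrix(2.5, 5, n))
  sol <- solve_velocity(D0, D48, rap)
  expect_equal(sol$base, (D48 - D0) / 48, tolerance = 1e-12)
  for (t in c(3, 6, 24)) {
    expect_equal(sol$intermediates[[paste0(t, "h")]],
                 D0 + (t / 48) * (D48 - D0), tolerance = 1e-12)
  }
  # explicit numbers: delta0 = 10, delta48 = 2 -> v0 = -1/6, linear path
  one0 <- matrix(c(0, 10, 10, 0), 2, 2)
  one48 <- matrix(c(0, 2, 2, 0), 2, 2)
  rap2 <- rap_timeseries(c(0, 3, 6, 24, 48), matrix(1, 5, 2))
  s <- solve_velocity(one0, one48, rap2)
  expect_equal(s$base[1, 2], -8 / 48)
  expect_equal(s$intermediates[["3h"]][1, 2], 9.5)
  expect_equal(s$intermediates[["6h"]][1, 2], 9.0)
  expect_equal(s$intermediates[["24h"]][1, 2], 6.0)
})

test_that("velocity model solves the stipulated ratio chain by hand", {
  # r1 = 2, r2 = 1, r3 = 0.5, displacement 6.9:
  # denominator 3 + 3*2 + 18*2 + 24*1 = 69, so v0 = 0.1
  rapv <- rbind(c(1, 1), c(2, 2), c(2, 2), c(1, 1), c(1, 1))
  rap <- rap_timeseries(c(0, 3, 6, 24, 48), rapv)
  D0 <- matrix(c(0, 10, 10, 0), 2, 2)
  D48 <- matrix(c(0, 16.9, 16.9, 0), 2, 2)
  s <- solve_velocity(D0, D48, rap)
  expect_equal(s$base[1, 2], 0.1, tolerance = 1e-12)
  expect_equal(s$intermediates[["3h"]][1, 2], 10.3)
  expect_equal(s$intermediates[["6h"]][1, 2], 10.9)
  expect_equal(s$intermediates[["24h"]][1, 2], 14.5)
  # reconstructed end point
  expect_equal(s$intermediates[["24h"]][1, 2] +
                 s$period_rates[["24h"]][1, 2] * 24, 16.9)
})

test_that("both models conserve total displacement per pair", {
  n <- 40
  set.seed(61)
  D0 <- rand_symmetric(n, 5, 30)
  D48 <- rand_symmetric(n, 2, 25)
  rap <- make_rap_timeseries(n, 11)
  sv <- solve_velocity(D0, D48, rap)
  disp <- Reduce(`+`, Map(`*`, sv$period_rates, dt_grid))
  expect_lt(max(abs(disp - (D48 - D0))), 1e-9)

  sa <- solve_acceleration(D0, D48, rap)
  dispA <- Reduce(`+`, Map(function(v, a, dt) v * dt + 0.5 * a * dt^2,
                           sa$period_velocities, sa$period_rates,
                           as.list(dt_grid)))
  expect_lt(max(abs(dispA - (D48 - D0))), 1e-9)

  # zero displacement gives zero rates and flat intermediates
  s0 <- solve_velocity(D0, D0, rap)
  expect_equal(max(abs(s0$base)), 0)
  expect_equal(s0$intermediates[["24h"]], D0, tolerance = 1e-12)
  a0 <- solve_acceleration(D0, D0, rap)
  expect_equal(max(abs(a0$base)), 0)
})

test_that("constant RAP reduces the acceleration model to uniform t^2", {
  n <- 6
  set.seed(62)
  D0 <- rand_symmetric(n, 8, 12)
  D48 <- rand_symmetric(n, 1, 4)
  rap <- rap_timeseries(c(0, 3, 6, 24, 48), matrix(4, 5, n))
  s <- solve_acceleration(D0, D48, rap)
  expect_equal(s$base, (D48 - D0) / 1152, tolerance = 1e-12)  # 48^2 / 2
  for (t in c(3, 6, 24)) {
    expect_equal(s$intermediates[[paste0(t, "h")]],
                 D0 + (t^2 / 48^2) * (D48 - D0), tolerance = 1e-12)
  }
})

test_that("acceleration ratio chain agrees with a symbolic recomputation", {
  # r1 = 2, r2 = r3 = 1: coefficient of a0 assembled independently
  rapv <- rbind(c(1, 1), c(2, 2), c(2, 2), c(2, 2), c(2, 2))
  rap <- rap_timeseries(c(0, 3, 6, 24, 48), rapv)
  D0 <- matrix(c(0, 5, 5, 0), 2, 2)
  D48 <- matrix(c(0, 12, 12, 0), 2, 2)
  g <- c(1, 2, 2, 2)             # per-period acceleration multipliers
  U <- cumsum(c(0, g * dt_grid))[1:4]  # period-start velocities (x a0)
  coef_a0 <- sum(U * dt_grid + 0.5 * g * dt_grid^2)
  s <- solve_acceleration(D0, D48, rap)
  expect_equal(s$base[1, 2], 7 / coef_a0, tolerance = 1e-12)
  # and against a brute-force numeric root find on the same equation
  f <- function(a0) {
    v <- 0; x <- 0
    for (p in 1:4) {
      x <- x + v * dt_grid[p] + 0.5 * g[p] * a0 * dt_grid[p]^2
      v <- v + g[p] * a0 * dt_grid[p]
    }
    x - 7
  }
  root <- uniroot(f, c(0, 1), tol = 1e-14)$root
  expect_equal(s$base[1, 2], root, tolerance = 1e-10)
})

test_that("RAP scaling equivariance: only intensity ratios matter", {
  n <- 10
  set.seed(63)
  D0 <- rand_symmetric(n, 5, 15)
  D48 <- rand_symmetric(n, 2, 10)
  rap <- make_rap_timeseries(n, 4)
  scaled <- rap_timeseries(rap$times, rap$values * 123.4)
  for (solver in list(solve_velocity, solve_acceleration)) {
    a <- solver(D0, D48, rap)
    b <- solver(D0, D48, scaled)
    expect_equal(a$base, b$base, tolerance = 1e-9)
    expect_equal(a$intermediates, b$intermediates, tolerance = 1e-9)
  }
})

test_that("monotone interpolation for one-signed velocity displacement", {
  n <- 12
  set.seed(64)
  D0 <- rand_symmetric(n, 10, 20)
  D48 <- D0 - rand_symmetric(n, 1, 5)  # all pairs strictly closing
  D48[D48 <= 0.5] <- 0.5
  diag(D48) <- 0
  rap <- make_rap_timeseries(n, 6)
  s <- solve_velocity(D0, D48, rap)
  up <- upper.tri(D0)
  for (m in s$intermediates) {
    expect_true(all(m[up] <= D0[up] + 1e-12))
    expect_true(all(m[up] >= D48[up] - 1e-12))
  }
})

test_that("clamping floors overshoot pairs and spares the end points", {
  n <- 4
  D0 <- rand_symmetric(n, 5, 8)
  D48 <- rand_symmetric(n, 5, 8)
  rap <- make_rap_timeseries(n, 2)
  s <- solve_velocity(D0, D48, rap)
  s$intermediates[["24h"]][1, 2] <- -0.3
  s$intermediates[["24h"]][2, 1] <- -0.3
  expect_message(cl <- clamp_intermediates(s, 1e-6), "clamped 1")
  expect_equal(cl$intermediates[["24h"]][1, 2], 1e-6)
  expect_equal(cl$clamped, 1L)
  expect_equal(cl$delta0, s$delta0)
  expect_equal(cl$delta48, s$delta48)
  # no overshoot: identity
  s2 <- clamp_intermediates(solve_velocity(D0, D48, rap))
  expect_equal(s2$clamped, 0L)
})

test_that("rescaling caps intermediates at the lattice diagonal", {
  n <- 5
  D0 <- rand_symmetric(n, 2, 4)
  D48 <- rand_symmetric(n, 2, 4)
  rap <- make_rap_timeseries(n, 3)
  s <- clamp_intermediates(solve_velocity(D0, D48, rap))
  mx <- n * sqrt(3)
  # force one intermediate over the bound
  s$intermediates[["6h"]] <- s$intermediates[["6h"]] /
    max(s$intermediates[["6h"]]) * 1.2 * mx
  expect_message(tg <- rescale_intermediates(s, n), "rescaled")
  expect_lte(max(tg[["6h"]]$delta_prime), mx * (1 + 1e-9))
  expect_equal(unname(attr(tg, "scales")["6h"]), 1 / 1.2, tolerance = 1e-9)
  expect_equal(unname(attr(tg, "scales")["3h"]), 1)
  # within-bound matrices pass through unchanged
  expect_equal(tg[["3h"]]$delta_prime, s$intermediates[["3h"]],
               tolerance = 1e-12)
})

test_that("the full interpolation pipeline feeds the annealer", {
  set.seed(65)
  fx0 <- make_ground_truth(20, "two_domain")
  d0 <- as.matrix(dist(conf_coords(fx0)))
  set.seed(66)
  fx48 <- make_ground_truth(20, "random_walk_lattice")
  d48 <- as.matrix(dist(conf_coords(fx48)))
  sc <- 20 * sqrt(3) / max(d0, d48)
  rap <- make_rap_timeseries(20, 10)
  sol <- xci_interpolate(d0 * sc, d48 * sc, rap, model = "velocity")
  for (tg in sol$targets) {
    set.seed(67)
    f <- fit_structure(tg, anneal_schedule(max_temps = 30,
                                           stop_after_failed = 1))
    expect_true(oracle_audit(coef(f), side_of(f$conformation)))
  }
})
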
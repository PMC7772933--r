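rigid_copy <- function(X, theta = 0.8, shift = c(4, -7, 2)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta),  cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  X %*% R + matrix(shift, nrow(X), 3, byrow = TRUE)
}

test_that("superposition recovers rigid transforms exactly", {
  set.seed(71)
  X <- matrix(rnorm(60), ncol = 3) * 4
  expect_lt(superpose(X, X)$rmsd, 1e-12)
  expect_equal(superpose(X, X)$rotation, diag(3), tolerance = 1e-9)
  Y <- rigid_copy(X)
  sp <- superpose(X, Y)
  expect_lt(sp$rmsd, 1e-9)
  expect_lt(max(abs(sp$transformed - X)), 1e-9)
  # proper rotation: mirror images are not identified
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_warning(superpose(cbind(1:10, 0, 0), cbind(1:10, 0, 0)),
                 "collinear")
})

test_that("superposition RMSD agrees with an independent reference", {
  set.seed(72)
  X <- matrix(rnorm(36), ncol = 3) * 3
  Y <- X + matrix(rnorm(36), ncol = 3)
  got <- superpose(X, Y)$rmsd
  ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("TM-score is 1 for identical and rigidly moved copies", {
  set.seed(73)
  X <- conf_coords(init_chain(40))
  expect_equal(tm_score(X, X), 1.0)
  expect_equal(tm_score(X, rigid_copy(X)), 1.0, tolerance = 1e-6)
  expect_error(tm_score(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("TM-score is symmetric, bounded, and decays under heavy noise", {
  set.seed(74)
  X <- conf_coords(init_chain(50))
  d0 <- 1.24 * (50 - 15)^(1 / 3) - 1.8
  for (sigma in c(0.5, 2, 10 * d0)) {
    Y <- X + matrix(rnorm(length(X), 0, sigma), ncol = 3)
    a <- tm_score(X, Y)
    b <- tm_score(Y, X)
    expect_lt(abs(a - b), 1e-6)
    expect_true(a > 0 && a <= 1)
  }
  # noise far above d0 destroys similarity
  Ybad <- X + matrix(rnorm(length(X), 0, 20 * d0), ncol = 3)
  expect_lt(tm_score(X, Ybad), 0.3)
})

test_that("Q-score averages pairwise TM-scores", {
  # stipulated pool: TM(1,2) = 0.8, TM(1,3) = 0.6, TM(2,3) = 0.9
  tm <- matrix(c(1, 0.8, 0.6,
                 0.8, 1, 0.9,
                 0.6, 0.9, 1), 3, 3)
  expect_equal(q_score(tm), c(0.7, 0.85, 0.75))
  # identical structures give Q = 1 for everyone
  set.seed(75)
  X <- conf_coords(init_chain(20))
  pool <- list(X, X, X, X)
  expect_equal(q_score(pool), rep(1, 4))
  expect_error(q_score(list(X)), "at least 2")
  # ranking is invariant to member order
  perm <- c(3, 1, 2)
  expect_equal(q_score(tm[perm, perm]), q_score(tm)[perm])
})

test_that("ensembles are reproducible and rank by Q then loss", {
  tg <- small_targets(20, seed = 81)
  e1 <- run_ensemble(tg, n_runs = 3, seeds = c(5, 6, 7))
  e2 <- run_ensemble(tg, n_runs = 3, seeds = c(5, 6, 7))
  expect_identical(coef(e1$members[[1]]), coef(e2$members[[1]]))
  expect_identical(e1$q_scores, e2$q_scores)
  expect_equal(sort(e1$order), 1:3)
  expect_equal(e1$q_scores[e1$order[1]], max(e1$q_scores))
  expect_length(top_structures(e1, 2), 2)
  expect_error(run_ensemble(tg, n_runs = 2, seeds = c(1, 1)), "distinct")
})

test_that("distance correlation matches the textbook formula", {
  set.seed(76)
  conf <- init_chain(20)
  d <- as.matrix(dist(conf_coords(conf)))
  # exact targets give r = 1
  expect_equal(distance_correlation(conf, d)$r, 1.0)
  # affine transforms of the targets leave r unchanged
  expect_equal(distance_correlation(conf, 2.5 * d + 1)$r, 1.0)
  # random targets against the two-pass oracle
  tg <- rand_symmetric(20, 1, 30)
  got <- distance_correlation(conf, tg)
  up <- upper.tri(d)
  expect_equal(got$r, oracle_pearson(d[up], tg[up]), tolerance = 1e-12)
  expect_true(got$p_value >= 0 && got$p_value <= 1)
  expect_error(distance_correlation(conf, matrix(1, 20, 20) - diag(20)),
               "constant")
})
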
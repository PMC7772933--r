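# Independent naive reference implementations used as oracles.
# Deliberately written as plain double loops, sharing no code with the
# package internals.

oracle_loss <- function(xyz, delta, w) {
  n <- nrow(xyz)
  L <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      L <- L + w * (d - delta[i, j])^2 / delta[i, j]^2
    }
  }
  L
}

oracle_impute <- function(C, mu, d0, normalization = "kernel") {
  n <- nrow(C)
  out <- C
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || C[i, j] != 0) next
      num <- 0; wsum <- 0; cnt <- 0
      for (a in max(1, i - d0):min(n, i + d0)) {
        for (b in max(1, j - d0):min(n, j + d0)) {
          if (C[a, b] > 0) {
            wt <- exp(-mu * ((a - i)^2 + (b - j)^2))
            num <- num + C[a, b] * wt
            wsum <- wsum + wt
            cnt <- cnt + 1
          }
        }
      }
      if (cnt > 0)
        out[i, j] <- if (normalization == "kernel") num / wsum else num / cnt
    }
  }
  # mirror the upper triangle like the production code
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

oracle_audit <- function(xyz, side) {
  n <- nrow(xyz)
  if (any(xyz < 0) || any(xyz >= side)) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (j == i + 1) {
        if (d2 < 2 || d2 > 10 || d2 == 8) return(FALSE)
      } else {
        if (d2 < 2 || d2 == 8) return(FALSE)
      }
    }
  }
  TRUE
}

oracle_pearson <- function(x, y) {
  # textbook two-pass formula
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

rand_symmetric <- function(n, min = 0.5, max = 5) {
  m <- matrix(runif(n * n, min, max), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

conf_coords <- function(conf) {
  x <- unclass(conf)
  attr(x, "side") <- NULL
  attr(x, "bins") <- NULL
  attr(x, "domains") <- NULL
  attr(x, "applied") <- NULL
  attr(x, "trials") <- NULL
  x
}

small_targets <- function(n, seed = 42) {
  set.seed(seed)
  conf <- init_chain(n)
  d <- as.matrix(dist(conf_coords(conf)))
  target_dist(d * (n * sqrt(3) / max(d)), n)
}

side_of <- function(conf) attr(conf, "side")
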
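#' Impute zero Hi-C contacts with a 2D Gaussian kernel
#'
#' Population Hi-C matrices contain many zero entries that cannot be
#' converted to target distances (the c^(-1/3) power law would give
#' infinity). Each off-diagonal zero entry `(i,j)` is replaced by a 2D
#' Gaussian-kernel estimate over the non-zero entries in its sequential
#' neighbourhood — all `(a,b)` with `|a-i| <= d0`, `|b-j| <= d0` and
#' `c_ab > 0`, with weights `w_ab = exp(-mu ((a-i)^2 + (b-j)^2))`:
#'
#' \deqn{c'_{ij} = \frac{\sum_{(a,b)} c_{ab} w_{ab}}{\sum_{(a,b)} w_{ab}}
#'   \quad \textrm{("kernel")}, \qquad
#'   c'_{ij} = \frac{1}{n'} \sum_{(a,b)} c_{ab} w_{ab}
#'   \quad \textrm{("count")}}
#'
#' The default `"kernel"` form is the standard kernel-weighted (Nadaraya–
#' Watson) average: it reproduces a locally constant matrix exactly, so an
#' imputed entry is always on the scale of its neighbours. The `"count"`
#' form divides by the number `n'` of contributing pairs instead of the
#' weight sum; because distant window entries carry near-zero weight but
#' still count toward `n'`, it shrinks imputed values well below their
#' neighbours (by the mean kernel weight, about 15-fold at `mu = 1`,
#' `d0 = 3`) and is kept only for comparison with the count-normalized
#' description of the estimator. See the package vignette.
#'
#' `mu` controls how much influence a neighbour exerts (larger `mu`,
#' smaller influence of distant neighbours); `d0` is the window radius in
#' bins. Non-zero entries and the diagonal are left untouched; zeros with
#' an empty window stay zero and are reported in the `unimputed` field.
#' Symmetry is enforced by computing the upper triangle and mirroring.
#'
#' @param m a [contact_matrix()] (or plain symmetric matrix).
#' @param mu positive kernel decay weight.
#' @param d0 positive integer window radius in bins; the default grows with
#'   the fraction of zero entries, `max(3, ceiling(10 * zero_fraction))`.
#' @param normalization `"kernel"` (divide by the summed kernel weights,
#'   default) or `"count"` (divide by the number of contributing pairs).
#' @return A [contact_matrix()] whose `unimputed` field is a symmetric
#'   logical matrix marking pairs that could not be imputed.
#' @export
impute_zeros <- function(m, mu = 1.0, d0 = NULL,
                         normalization = c("kernel", "count")) {
  normalization <- match.arg(normalization)
  cm <- if (inherits(m, "contact_matrix")) m else contact_matrix(m)
  C <- cm$counts
  n <- nrow(C)
  if (mu <= 0) stop_fmt("mu must be positive")
  Cw <- C
  Cw[is.na(Cw)] <- 0  # masked bins contribute nothing to windows
  zf <- mean(Cw[upper.tri(Cw)] == 0)
  d0 <- d0 %||% max(3L, ceiling(10 * zf))
  d0 <- as.integer(d0)
  if (d0 < 1) stop_fmt("d0 must be >= 1")

  pos <- (Cw > 0) * 1
  num <- matrix(0, n, n)   # sum of kernel-weighted neighbour counts
  den <- matrix(0, n, n)   # kernel weight sum over contributing neighbours
  cnt <- matrix(0, n, n)   # n': number of contributing neighbours
  for (da in -d0:d0) {
    for (db in -d0:d0) {
      wgt <- exp(-mu * (da * da + db * db))
      sp <- shift_cols(shift_rows(pos, da), db)
      num <- num + wgt * shift_cols(shift_rows(Cw, da), db)
      den <- den + wgt * sp
      cnt <- cnt + sp
    }
  }
  divisor <- if (normalization == "kernel") den else cnt
  imput <- ifelse(cnt > 0, num / pmax(divisor, .Machine$double.xmin), 0)

  out <- C
  zero <- !is.na(C) & C == 0
  zero[lower.tri(zero, diag = TRUE)] <- FALSE  # upper triangle, no diagonal
  out[zero] <- imput[zero]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]  # mirror

  unimp <- matrix(FALSE, n, n)
  unimp[zero & cnt == 0] <- TRUE
  unimp <- unimp | t(unimp)
  n_unimp <- sum(unimp[upper.tri(unimp)])
  if (n_unimp > 0)
    message(sprintf("%d pairs had empty imputation windows and remain zero",
                    n_unimp))
  contact_matrix(out, cm$bins, cm$mask, unimputed = unimp)
}

# shift matrix rows by k (positive: take rows further down), zero-padding
shift_rows <- function(m, k) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  if (k >= 0) {
    if (k < n) out[1:(n - k), ] <- m[(1 + k):n, , drop = FALSE]
  } else {
    if (-k < n) out[(1 - k):n, ] <- m[1:(n + k), , drop = FALSE]
  }
  out
}

shift_cols <- function(m, k) t(shift_rows(t(m), k))
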
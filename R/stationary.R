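#' Analytic stationary distribution of the karyotype walk
#'
#' On the unbounded karyograph the fusion/fission/centromere-movement
#' walk is reversible, and detailed balance gives the stationary
#' probability of karyotype `(x, y)` as
#' \deqn{\pi(x, y) \propto \frac{(2K_f)^y K_i^{-x}}{(2y-x)!\,(x-y)!},}
#' where `K_f = k2/k1` is the fission/fusion bias and `K_i = k4/k3` the
#' M-A/A-M bias. Summing over `x` for fixed `y` shows that the marginal
#' of the chromosome number is a zero-truncated Poisson with intensity
#' \deqn{\Lambda = 2 K_f (K_i + 1) / K_i^2,}
#' (normalizer `e^Lambda - 1`), and that the metacentric count given `y`
#' is Binomial(`y`, `1/(K_i+1)`). The distribution depends on the four
#' rates only through the ratios `K_f` and `K_i`.
#'
#' The distribution is evaluated on the truncation `y <= y_max` and
#' renormalized there. If the zero-truncated-Poisson tail mass beyond
#' `y_max` exceeds `1e-10` a warning notes that the truncation may be
#' too small.
#'
#' Polyploidization (`k5 > 0`) breaks the lattice balance; the
#' stationary distribution is only defined for the four-rate walk.
#'
#' @param K_f Fission/fusion bias `k2/k1` (> 0).
#' @param K_i M-A/A-M bias `k4/k3` (> 0).
#' @param y_max Truncation bound on the chromosome number.
#' @return An object of class `karyo_stationary`: a data frame with
#'   columns `x`, `y`, `prob`, plus attributes `K_f`, `K_i`, `Lambda`
#'   and `space`.
#' @seealso [stationary_numeric()], [stationary_moments()]
#' @examples
#' sd <- stationary_karyotype(16.5, 6.5, y_max = 30)
#' sum(sd$prob)
#' @export
stationary_karyotype <- function(K_f, K_i, y_max = 35) {
  if (!is.finite(K_f) || !is.finite(K_i) || K_f <= 0 || K_i <= 0)
    stop("'K_f' and 'K_i' must be positive and finite")
  space <- karyo_states(y_max)
  lp <- space$y * log(2 * K_f) - space$x * log(K_i) -
    lfactorial(2 * space$y - space$x) - lfactorial(space$x - space$y)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  Lambda <- 2 * K_f * (K_i + 1) / K_i^2
  # tail mass of the zero-truncated Poisson beyond the truncation
  tail <- stats::ppois(y_max, Lambda, lower.tail = FALSE) / (1 - exp(-Lambda))
  if (tail > 1e-10)
    warning(sprintf(
      "truncation y_max = %d leaves tail mass %.3g; increase y_max", y_max, tail))
  out <- data.frame(x = space$x, y = space$y, prob = p)
  attr(out, "K_f") <- K_f
  attr(out, "K_i") <- K_i
  attr(out, "Lambda") <- Lambda
  attr(out, "space") <- space
  class(out) <- c("karyo_stationary", "data.frame")
  out
}

#' @export
print.karyo_stationary <- function(x, ...) {
  m <- stationary_moments(x)
  cat(sprintf(
    "Stationary karyotype distribution: K_f = %.4g, K_i = %.4g, Lambda = %.4g\n",
    attr(x, "K_f"), attr(x, "K_i"), attr(x, "Lambda")))
  cat(sprintf("  chromosome number y: mean %.3f, var %.3f, mode %d\n",
              m["mean_y"], m["var_y"], m["mode_y"]))
  cat(sprintf("  arm number x:        mean %.3f, var %.3f, mode %d\n",
              m["mean_x"], m["var_x"], m["mode_x"]))
  invisible(x)
}

#' Numeric stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a least-squares linear solve; the
#' independent oracle for [stationary_karyotype()].
#'
#' @param Q Generator matrix (square; typically from
#'   [karyo_rate_matrix()] with `k5 = 0`).
#' @param tol Residual tolerance on `max |pi Q|`.
#' @return Numeric probability vector in state order, with attribute
#'   `residual`.
#' @export
stationary_numeric <- function(Q, tol = 1e-10) {
  if (isTRUE(attr(Q, "polyploid")))
    stop("stationary distribution is undefined with polyploidization (k5 > 0)")
  n <- nrow(Q)
  A <- rbind(t(as.matrix(Q)), rep(1, n))
  if (max(abs(A)) == 0) stop("all-zero generator has no unique stationary distribution")
  p <- qr.solve(A, c(rep(0, n), 1))
  resid <- max(abs(as.numeric(p %*% Q)))
  if (resid > tol || any(p < -tol))
    stop("no unique stationary distribution found (generator reducible?)")
  p[p < 0] <- 0
  p <- p / sum(p)
  attr(p, "residual") <- resid
  p
}

#' Moments of the stationary karyotype distribution
#'
#' Closed-form moments from the analytic structure: `y` is
#' zero-truncated Poisson(`Lambda`) and the metacentric count given `y`
#' is Binomial(`y`, `p`) with `p = 1/(K_i + 1)`, so `x = y + n_M` has
#' `E[x] = (1 + p) E[y]` and
#' `Var[x] = p(1-p) E[y] + (1+p)^2 Var[y]`. Modes are taken as the
#' argmax over the evaluated lattice, ties broken toward the smaller
#' `(y, x)` in lexicographic order.
#'
#' @param sd A `karyo_stationary` object.
#' @return Named numeric vector with `mean_x`, `var_x`, `mode_x`,
#'   `mean_y`, `var_y`, `mode_y`.
#' @export
stationary_moments <- function(sd) {
  stopifnot(inherits(sd, "karyo_stationary"))
  Lambda <- attr(sd, "Lambda")
  K_i <- attr(sd, "K_i")
  p <- 1 / (K_i + 1)
  mean_y <- Lambda / (1 - exp(-Lambda))
  var_y <- mean_y * (1 + Lambda - mean_y)
  mean_x <- (1 + p) * mean_y
  var_x <- p * (1 - p) * mean_y + (1 + p)^2 * var_y
  # lattice mode; rows are already sorted by (y, x) so which.max is the
  # lexicographically smallest maximizer
  i <- which.max(sd$prob)
  # marginal modes
  ymarg <- tapply(sd$prob, sd$y, sum)
  xmarg <- tapply(sd$prob, sd$x, sum)
  mode_y <- as.integer(names(ymarg)[which.max(ymarg)])
  mode_x <- as.integer(names(xmarg)[which.max(xmarg)])
  c(mean_x = mean_x, var_x = var_x, mode_x = mode_x,
    mean_y = mean_y, var_y = var_y, mode_y = mode_y,
    mode_joint_x = sd$x[i], mode_joint_y = sd$y[i])
}
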
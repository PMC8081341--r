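#' Enumerate the karyograph state space
#'
#' A karyotype is summarised by its haploid arm number `x` and haploid
#' chromosome number `y`. Because every chromosome contributes one arm
#' (acrocentric) or two arms (metacentric), any karyotype satisfies
#' `y <= x <= 2y`. The state space for a given maximum chromosome number
#' `y_max` is the set of all lattice points with `1 <= y <= y_max` and
#' `y <= x <= 2y`, of size `sum(y + 1)` over `y = 1..y_max` (665 states
#' for `y_max = 35`).
#'
#' States are ordered by ascending `y`, then ascending `x`, and indexed
#' densely from 1; the ordering is deterministic so that serialized state
#' indices are stable across runs.
#'
#' @param y_max Maximum haploid chromosome number (integer >= 1).
#' @return An object of class `karyo_space`: a data frame with columns
#'   `x` and `y` (one row per state, in canonical order) and attribute
#'   `y_max`.
#' @examples
#' sp <- karyo_states(8)
#' nrow(sp)  # 44
#' @export
karyo_states <- function(y_max) {
  if (length(y_max) != 1L || is.na(y_max) || y_max < 1 || y_max != floor(y_max))
    stop("'y_max' must be a single integer >= 1")
  y_max <- as.integer(y_max)
  y <- rep.int(seq_len(y_max), seq_len(y_max) + 1L)
  x <- unlist(lapply(seq_len(y_max), function(yy) yy:(2L * yy)), use.names = FALSE)
  sp <- data.frame(x = x, y = y)
  attr(sp, "y_max") <- y_max
  class(sp) <- c("karyo_space", "data.frame")
  sp
}

#' @export
print.karyo_space <- function(x, ...) {
  cat("Karyograph state space: y_max =", attr(x, "y_max"),
      "(", nrow(x), "states )\n")
  invisible(x)
}

#' Map karyotypes to state indices
#'
#' @param space A `karyo_space`.
#' @param x,y Vectors of arm and chromosome numbers (recycled together).
#' @return Integer indices into `space` (1-based); `NA` for karyotypes
#'   outside the space.
#' @export
state_index <- function(space, x, y) {
  stopifnot(inherits(space, "karyo_space"))
  y_max <- attr(space, "y_max")
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  ok <- !is.na(x) & !is.na(y) & y >= 1L & y <= y_max & x >= y & x <= 2L * y
  # states with chromosome number < y occupy sum_{k<y}(k+1) = y(y+1)/2 - 1 rows
  idx <- ifelse(ok, (y * (y + 1L)) %/% 2L - 1L + (x - y + 1L), NA_integer_)
  as.integer(idx)
}

#' Acrocentric and metacentric chromosome counts
#'
#' For a karyotype `(x, y)` the number of acrocentric chromosomes is
#' `n_A = 2y - x` and the number of metacentric chromosomes is
#' `n_M = x - y`; they satisfy `n_A + n_M = y` and `n_A + 2 n_M = x`.
#'
#' @param x,y Arm and chromosome numbers (vectors, recycled).
#' @return A data frame with columns `n_A` and `n_M`.
#' @examples
#' chromosome_counts(47, 25)  # 3 acrocentric, 22 metacentric
#' @export
chromosome_counts <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n)
  y <- rep_len(as.integer(y), n)
  if (any(is.na(x) | is.na(y) | y < 1L | x < y | x > 2L * y))
    stop("invalid karyotype: need y >= 1 and y <= x <= 2y")
  data.frame(n_A = 2L * y - x, n_M = x - y)
}

#' Rate parameters of the karyotype walk
#'
#' Bundles the per-event rate coefficients (all per million years):
#' `k1` centric fusion per pair of acrocentrics, `k2` centric fission per
#' metacentric, `k3` A-M transition per acrocentric, `k4` M-A transition
#' per metacentric, and `k5` polyploidization per lineage (0 disables the
#' doubling jump). Speciation (`lambda`) and extinction (`mu`) rates may
#' be scalars (state-constant) or given per karyotype group via a focal
#' set (see [fit_karyotype_model()]).
#'
#' @param k1,k2,k3,k4 Non-negative rate coefficients.
#' @param k5 Polyploidization rate (default 0).
#' @param lambda,mu Speciation and extinction rates (default 0). Either
#'   scalars, or length-2 vectors `c(focal, other)` interpreted with a
#'   focal karyotype set.
#' @return An object of class `karyo_rates` (a named list).
#' @export
karyo_rates <- function(k1, k2, k3, k4, k5 = 0, lambda = 0, mu = 0) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("rate coefficients must be finite and >= 0")
  if (any(!is.finite(c(lambda, mu))) || any(c(lambda, mu) < 0))
    stop("'lambda' and 'mu' must be finite and >= 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
                 lambda = lambda, mu = mu),
            class = "karyo_rates")
}

#' @export
print.karyo_rates <- function(x, ...) {
  cat("Karyotype transition rates (per Myr):\n")
  cat(sprintf("  k1 (fusion)   = %.4g\n  k2 (fission)  = %.4g\n", x$k1, x$k2))
  cat(sprintf("  k3 (A-M)      = %.4g\n  k4 (M-A)      = %.4g\n", x$k3, x$k4))
  if (x$k5 > 0) cat(sprintf("  k5 (polyploid)= %.4g\n", x$k5))
  if (x$k1 > 0) cat(sprintf("  K_f = k2/k1   = %.4g\n", x$k2 / x$k1))
  if (x$k3 > 0) cat(sprintf("  K_i = k4/k3   = %.4g\n", x$k4 / x$k3))
  if (any(x$lambda > 0) || any(x$mu > 0))
    cat("  lambda =", format(x$lambda), " mu =", format(x$mu), "\n")
  invisible(x)
}

#' Build the transition-rate generator on the karyograph
#'
#' Transition rates out of karyotype `(x, y)` with `n_A = 2y - x`
#' acrocentrics and `n_M = x - y` metacentrics:
#' fusion to `(x, y-1)` at `k1 * n_A (n_A - 1) / 2`; fission to
#' `(x, y+1)` at `k2 * n_M`; A-M transition to `(x+1, y)` at `k3 * n_A`;
#' M-A transition to `(x-1, y)` at `k4 * n_M`. With `k5 > 0`,
#' whole-genome doubling jumps `(x, y)` to `(2x, 2y)` at rate `k5` for
#' every state with `2y <= y_max`. Moves that would leave the bounded
#' space (fission at `y = y_max`, doubling past `y_max`) have rate 0.
#'
#' @param space A `karyo_space`.
#' @param rates A `karyo_rates` object (only `k1..k5` are used).
#' @return A sparse `dgCMatrix` generator `Q` with zero row sums and the
#'   space attached as attribute `space`.
#' @examples
#' sp <- karyo_states(8)
#' Q <- karyo_rate_matrix(sp, karyo_rates(0.01, 0.01, 0.01, 0.01))
#' range(Matrix::rowSums(Q))  # 0, 0
#' @export
karyo_rate_matrix <- function(space, rates) {
  stopifnot(inherits(space, "karyo_space"), inherits(rates, "karyo_rates"))
  y_max <- attr(space, "y_max")
  n <- nrow(space)
  x <- space$x; y <- space$y
  nA <- 2L * y - x; nM <- x - y

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(i, j, r) {
    keep <- !is.na(j) & r > 0
    from <<- c(from, i[keep]); to <<- c(to, j[keep]); rate <<- c(rate, r[keep])
  }
  i <- seq_len(n)
  add(i, state_index(space, x, y - 1L), rates$k1 * nA * (nA - 1) / 2)
  add(i, state_index(space, x, y + 1L), rates$k2 * nM)
  add(i, state_index(space, x + 1L, y), rates$k3 * nA)
  add(i, state_index(space, x - 1L, y), rates$k4 * nM)
  if (rates$k5 > 0) {
    ok <- 2L * y <= y_max
    add(i[ok], state_index(space, 2L * x[ok], 2L * y[ok]),
        rep.int(rates$k5, sum(ok)))
  }
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  attr(Q, "space") <- space
  attr(Q, "polyploid") <- rates$k5 > 0
  Q
}

#' Serialize a state space and generator to plain text
#'
#' Writes the state list (index, x, y) and the generator in COO triplet
#' form to a JSON file, for debugging and cross-implementation
#' comparison.
#'
#' @param Q Generator from [karyo_rate_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_matrix <- function(Q, path) {
  space <- attr(Q, "space")
  coo <- Matrix::summary(Q)
  obj <- list(
    y_max = attr(space, "y_max"),
    states = data.frame(index = seq_len(nrow(space)) - 1L,
                        x = space$x, y = space$y),
    Q_coo = data.frame(i = coo$i - 1L, j = coo$j - 1L, rate = coo$x)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
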
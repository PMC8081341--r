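#' Transition probabilities over a branch
#'
#' Row `i` of `e^(Qt)`: the probability of each end state after
#' duration `t` starting from state `i`. Evaluation is piecewise, as in
#' the branch-fitting likelihood: for `0 <= t < 10` a degree-170 Taylor
#' polynomial of the exponential is accumulated on the row vector
#' (cheap for the sparse generator); for `10 <= t <= 15000` the matrix
#' exponential is computed directly; outside `[0, 15000]` the result is
#' undefined and a vector of `NA` is returned.
#'
#' @param Q Generator matrix.
#' @param i Starting state index.
#' @param t Branch duration (Myr).
#' @param method `"auto"` (piecewise rule), `"taylor"`, or `"expm"`.
#' @param degree Taylor degree (default 170).
#' @param t_max Upper validity bound (default 15000).
#' @return Probability vector over end states (or all `NA` out of
#'   range).
#' @export
transition_probability <- function(Q, i, t, method = c("auto", "taylor", "expm"),
                                   degree = 170L, t_max = 15000) {
  method <- match.arg(method)
  n <- nrow(Q)
  if (max(abs(Matrix::rowSums(Q))) > 1e-8) stop("Q rows must sum to zero")
  if (is.na(t) || t < 0 || t > t_max) return(rep(NA_real_, n))
  if (method == "auto") method <- if (t < 10) "taylor" else "expm"
  if (method == "taylor") {
    v <- numeric(n); v[i] <- 1
    term <- v
    for (k in seq_len(degree)) {
      term <- as.numeric(term %*% Q) * (t / k)
      v <- v + term
    }
    v[v < 0] <- 0
    v
  } else {
    as.numeric(Matrix::expm(Q * t)[i, ])
  }
}

#' Fit a branch length to a karyotype transition
#'
#' The model-scaled branch length `t_f` maximizing the transition
#' probability `[e^(Qt)]_{ij}` over `t in (0, t_max]`; it measures how
#' much evolutionary "time" the fitted process needs to make the
#' observed transition likely. If `i == j`, `t_f = 0` by definition.
#' Maximization starts from the conventional prior `t = 10` and a
#' log-spaced grid scan, then refines the best bracket with golden-
#' section search (the likelihood in `t` can in principle be
#' multimodal).
#'
#' @inheritParams transition_probability
#' @param j End state index.
#' @param grid_n Size of the log-spaced scan grid.
#' @return The fitted branch length `t_f` (attribute `logp`: log
#'   transition probability at the optimum), or `NA` if no positive
#'   probability is attainable.
#' @export
fit_branch_length <- function(Q, i, j, t_max = 15000, grid_n = 60L) {
  if (i == j) return(structure(0, logp = 0))
  fn <- function(t) {
    p <- transition_probability(Q, i, t, t_max = t_max)[j]
    if (is.na(p) || p <= 0) -Inf else log(p)
  }
  grid <- unique(sort(c(10, 10^seq(log10(0.01), log10(t_max), length.out = grid_n))))
  vals <- vapply(grid, fn, 0)
  if (all(!is.finite(vals))) return(structure(NA_real_, logp = -Inf))
  b <- which.max(vals)
  lo <- grid[max(1L, b - 1L)]; hi <- grid[min(length(grid), b + 1L)]
  opt <- stats::optimize(fn, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6 * hi)
  if (opt$objective >= vals[b])
    structure(opt$maximum, logp = opt$objective)
  else structure(grid[b], logp = vals[b])
}

#' Unexpected (1% tail) region of a state distribution
#'
#' Starting from the state with the smallest probability, probabilities
#' are accumulated in ascending order (ties by state index); the
#' unexpected region is the largest such prefix whose cumulative mass
#' stays strictly below `alpha`.
#'
#' @param prob Probability vector (sums to 1).
#' @param alpha Tail mass threshold (default 0.01).
#' @return Integer vector of state indices in the unexpected region
#'   (possibly empty).
#' @export
tail_region <- function(prob, alpha = 0.01) {
  ord <- order(prob, seq_along(prob))
  cum <- cumsum(prob[ord])
  k <- sum(cum < alpha)
  ord[seq_len(k)]
}

#' Classify a branch's karyotype transition
#'
#' Decision rule: if the descendant state `j` is inside the expected
#' (non-tail) region of `e^(Q t_g)` row `i`, the branch is "Expected".
#' Otherwise, if `j` is inside the expected region at the fitted length
#' `t_f`, the branch is "Rapid" when `t_f > t_g` and "Conservative"
#' when `t_g > t_f`. If `j` is in the tail under both durations, the
#' branch is "Unusual".
#'
#' @inheritParams transition_probability
#' @param j Descendant state index.
#' @param t_g Actual branch duration from the time-calibrated tree.
#' @param t_f Fitted branch length (computed via [fit_branch_length()]
#'   if missing).
#' @param alpha Tail mass threshold (default 0.01).
#' @return One of `"Expected"`, `"Conservative"`, `"Rapid"`,
#'   `"Unusual"`.
#' @export
classify_branch <- function(Q, i, j, t_g, t_f = NULL, alpha = 0.01,
                            t_max = 15000) {
  stopifnot(t_g >= 0)
  pg <- transition_probability(Q, i, t_g, t_max = t_max)
  if (anyNA(pg)) stop("branch duration out of the evaluable range")
  if (!(j %in% tail_region(pg, alpha))) return("Expected")
  if (is.null(t_f)) t_f <- as.numeric(fit_branch_length(Q, i, j, t_max = t_max))
  if (is.na(t_f)) return("Unusual")
  pf <- transition_probability(Q, i, t_f, t_max = t_max)
  if (!(j %in% tail_region(pf, alpha)))
    return(if (t_f > t_g) "Rapid" else "Conservative")
  "Unusual"
}

#' Annotate all branches of a reconstructed tree
#'
#' For every branch, takes the modal reconstructed karyotype of the
#' ancestral and descendant nodes (observed karyotypes at tips),
#' fits the model-scaled branch length (cached per unique transition),
#' and classifies the branch.
#'
#' @param fit A `karyo_fit` (its transition rates define `Q`).
#' @param asr The matching `karyo_asr`.
#' @param alpha Tail mass threshold.
#' @param t_max Upper bound on fittable branch lengths.
#' @return A data frame with one row per branch: ancestor and
#'   descendant modes, `t_g`, `t_f`, `category`, `is_terminal`.
#' @export
annotate_branches <- function(fit, asr, alpha = 0.01, t_max = 15000) {
  stopifnot(inherits(fit, "karyo_fit"), inherits(asr, "karyo_asr"))
  tree <- asr$tree
  space <- asr$space
  Q <- karyo_rate_matrix(space, fit$rates)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  mode_state <- integer(nn)
  mode_state[asr$summary$node] <- state_index(space, asr$summary$mode_x,
                                              asr$summary$mode_y)
  mode_state[seq_len(ntip)] <- asr$tip_states

  cache <- new.env(parent = emptyenv())
  tf_for <- function(i, j) {
    key <- paste(i, j)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- as.numeric(fit_branch_length(Q, i, j, t_max = t_max))
      cache[[key]] <- v
    }
    v
  }

  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  res <- lapply(seq_len(nrow(tree$edge)), function(e) {
    i <- mode_state[parent[e]]; j <- mode_state[child[e]]
    t_g <- tree$edge.length[e]
    t_f <- tf_for(i, j)
    cat_ <- classify_branch(Q, i, j, t_g, t_f, alpha = alpha, t_max = t_max)
    data.frame(edge = e, parent = parent[e], child = child[e],
               anc_x = space$x[i], anc_y = space$y[i],
               des_x = space$x[j], des_y = space$y[j],
               t_g = t_g, t_f = t_f, category = cat_,
               is_terminal = child[e] <= ntip)
  })
  do.call(rbind, res)
}
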
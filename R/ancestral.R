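#' Marginal ancestral-state reconstruction
#'
#' For every internal node, the marginal posterior distribution of its
#' karyotype given all tip data and the fitted model. Computed by a
#' down pass (the pruning partials) followed by an up pass propagating
#' the "rest of tree" likelihood through the transpose of each branch
#' channel; the node marginal is the normalized elementwise product of
#' the two. For Mk-n fits and MuSSE fits with state-constant
#' diversification the branch channel is `e^(Qt)` (state-independent
#' scalars cancel in the normalization); for state-dependent
#' diversification (M2/M3) the linear clade-likelihood propagator is
#' rebuilt per branch by integrating the D equations with the
#' extinction profile fixed, which makes the pinned-node likelihoods
#' exact.
#'
#' @param fit A converged `karyo_fit`.
#' @param force Reconstruct even if the optimizer did not converge.
#' @return An object of class `karyo_asr`: a list with `prob`
#'   (matrix, internal nodes x states), `nodes` (ape node ids),
#'   `summary` (data frame: node, mode x/y, mean x/y), plus the space
#'   and tree.
#' @export
marginal_asr <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "karyo_fit"))
  if (!fit$converged && !force)
    stop("fit did not converge; use force = TRUE to reconstruct anyway")
  space <- fit$space
  n <- nrow(space)
  Q <- karyo_rate_matrix(space, fit$rates)
  lm <- state_vectors(space, fit$rates, fit$focal_idx)

  if (fit$method == "mkn") {
    det <- mkn_loglik(fit$tree, fit$tip_states, Q, root = fit$root,
                      details = TRUE)
    lambda_join <- NULL
  } else {
    det <- musse_loglik(fit$tree, fit$tip_states, Q, lm$lambda, lm$mu,
                        sampling_f = fit$sampling_f, root = fit$root,
                        condition_surv = fit$condition_surv, details = TRUE)
    lambda_join <- if (isTRUE(det$closed)) NULL else lm$lambda
  }
  asr_from_details(det, Q, space, fit$tree, lambda_join)
}

asr_from_details <- function(det, Q, space, tree, lambda_join = NULL) {
  po <- det$po
  n <- nrow(space)
  nn <- po$ntip + po$nnode
  edges <- po$edge

  ode_mode <- isFALSE(det$closed) && !is.null(det$E)
  if (ode_mode) {
    # per-edge channel matrices by column-wise integration of the
    # linear D system with the branch's extinction profile
    Phi <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      child <- edges[e, 2L]
      t_e <- po$length[e]
      Phi[[e]] <- vapply(seq_len(n), function(k) {
        D0 <- numeric(n); D0[k] <- 1
        sse_branch_ode(Q, det$lambda, parms_mu(det), det$E[, child], D0,
                       t_e, det$rtol, det$atol)$D
      }, numeric(n))
    }
    M <- vapply(seq_len(nrow(edges)), function(e) {
      m <- as.numeric(Phi[[e]] %*% det$D[, edges[e, 2L]])
      m / max(sum(m), .Machine$double.xmin)
    }, numeric(n))
  } else {
    M <- det$M
    prop <- det$prop
  }

  children <- split(seq_len(nrow(edges)), edges[, 1L])
  U <- matrix(0, n, nn)
  Droot <- det$D[, po$root]
  U[, po$root] <- if (det$root == "fitzjohn") Droot / sum(Droot) else rep(1 / n, n)

  for (e in rev(seq_len(nrow(edges)))) {  # reverse postorder = preorder
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    sibs <- setdiff(children[[as.character(parent)]], e)
    v <- U[, parent]
    for (s in sibs) v <- v * M[, s]
    if (!is.null(lambda_join) && length(sibs) && !all(det$lambda == 0))
      v <- v * det$lambda^length(sibs)
    u <- if (ode_mode) as.numeric(crossprod(Phi[[e]], v))
         else prop_apply_t(prop, po$length[e], v)
    su <- sum(u)
    U[, child] <- if (su > 0) u / su else u
  }

  internal <- po$ntip + seq_len(po$nnode)
  prob <- matrix(0, length(internal), n)
  for (i in seq_along(internal)) {
    p <- det$D[, internal[i]] * U[, internal[i]]
    prob[i, ] <- p / sum(p)
  }
  mode_i <- apply(prob, 1, which.max)  # states sorted by (y, x): ties small
  summ <- data.frame(node = internal,
                     mode_x = space$x[mode_i], mode_y = space$y[mode_i],
                     mean_x = as.numeric(prob %*% space$x),
                     mean_y = as.numeric(prob %*% space$y))
  structure(list(prob = prob, nodes = internal, summary = summ,
                 space = space, tree = tree, tip_states = det$ts),
            class = "karyo_asr")
}

parms_mu <- function(det) {
  # state mu vector is implicit in the stored ODE details
  if (!is.null(det$mu)) det$mu else attr(det, "mu")
}

#' @export
print.karyo_asr <- function(x, ...) {
  cat("Marginal ancestral karyotype reconstruction:",
      nrow(x$prob), "internal nodes,", ncol(x$prob), "states\n")
  root <- 1L
  rs <- x$summary[root, ]
  cat(sprintf("  root (MRCA) mode (%d, %d); mean x %.2f, mean y %.2f\n",
              rs$mode_x, rs$mode_y, rs$mean_x, rs$mean_y))
  invisible(x)
}

#' Credible-range summary of a node's karyotype distribution
#'
#' Default construction (`method = "credible"`): grow the smallest
#' credible set by descending probability (ties toward the smaller
#' state index) until the cumulative mass reaches `coverage`, then
#' report the min/max chromosome and arm number over that set. The
#' alternative `method = "marginal"` reports equal-tail quantile ranges
#' of the independent marginals of `y` and `x`, for sensitivity
#' analysis; output labels say which construction was used.
#'
#' @param prob Probability vector over the states of `space` (or a
#'   `karyo_asr` plus node index, see `node`).
#' @param space A `karyo_space` matching `prob`.
#' @param coverage Target coverage (default 0.95).
#' @param method `"credible"` or `"marginal"`.
#' @return Named vector `y_min`, `y_max`, `x_min`, `x_max` with
#'   attribute `method`.
#' @export
range_summary <- function(prob, space, coverage = 0.95,
                          method = c("credible", "marginal")) {
  method <- match.arg(method)
  stopifnot(length(prob) == nrow(space))
  if (method == "credible") {
    ord <- order(-prob, seq_along(prob))
    k <- which(cumsum(prob[ord]) >= coverage - 1e-12)[1]
    if (is.na(k)) k <- length(prob)
    set <- ord[seq_len(k)]
    out <- c(y_min = min(space$y[set]), y_max = max(space$y[set]),
             x_min = min(space$x[set]), x_max = max(space$x[set]))
  } else {
    qr_ <- function(vals) {
      m <- tapply(prob, vals, sum)
      v <- as.integer(names(m))
      cdf <- cumsum(m)
      lo <- v[which(cdf >= (1 - coverage) / 2)[1]]
      hi <- v[which(cdf >= 1 - (1 - coverage) / 2)[1]]
      c(lo, hi)
    }
    ry <- qr_(space$y); rx <- qr_(space$x)
    out <- c(y_min = ry[1], y_max = ry[2], x_min = rx[1], x_max = rx[2])
  }
  attr(out, "method") <- method
  out
}

#' Detect polyploidization events on reconstructed branches
#'
#' A branch is flagged as a possible whole-genome doubling when both
#' the chromosome number and the arm number increase more than 1.4-fold
#' from the ancestral node's modal karyotype to the descendant's
#' (observed karyotypes are used at tips).
#'
#' @param asr A `karyo_asr` (typically from an M4 fit).
#' @param fold Fold-change threshold (default 1.4).
#' @return Data frame of edges: `edge`, `parent`, `child`, parent and
#'   child modal `(x, y)`, and logical `polyploidization`.
#' @export
detect_polyploidization <- function(asr, fold = 1.4) {
  stopifnot(inherits(asr, "karyo_asr"))
  tree <- asr$tree
  space <- asr$space
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  mode_x <- mode_y <- integer(nn)
  mode_x[asr$summary$node] <- asr$summary$mode_x
  mode_y[asr$summary$node] <- asr$summary$mode_y
  ts <- asr$tip_states
  mode_x[seq_len(ntip)] <- space$x[ts]
  mode_y[seq_len(ntip)] <- space$y[ts]
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  flag <- mode_y[child] > fold * mode_y[parent] &
    mode_x[child] > fold * mode_x[parent]
  data.frame(edge = seq_len(nrow(tree$edge)), parent = parent, child = child,
             parent_x = mode_x[parent], parent_y = mode_y[parent],
             child_x = mode_x[child], child_y = mode_y[child],
             polyploidization = flag)
}
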
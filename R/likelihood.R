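# Propagator machinery ------------------------------------------------------
#
# Both the Mk-n pruning likelihood and the state-constant SSE fast path
# reduce every branch to the action of e^(Qt) on a vector. For a fixed Q
# we eigendecompose once and apply V exp(dt) V^-1 v per branch in O(n^2);
# if the eigenbasis is ill-conditioned we fall back to Matrix::expm with
# a cache keyed by rounded branch length.

make_propagator <- function(Q) {
  n <- nrow(Q)
  Qd <- as.matrix(Q)
  eg <- tryCatch(eigen(Qd), error = function(e) NULL)
  use_eigen <- FALSE
  V <- Vinv <- values <- NULL
  if (!is.null(eg)) {
    V <- eg$vectors
    Vinv <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vinv)) {
      # accept the eigenbasis only if it reproduces e^(Q) accurately
      kappa <- max(abs(Vinv)) * max(abs(V))
      use_eigen <- is.finite(kappa) && kappa < 1e10
      values <- eg$values
    }
  }
  cache <- new.env(parent = emptyenv())
  list(Q = Q, Qd = Qd, n = n, use_eigen = use_eigen,
       V = V, Vinv = Vinv, values = values, cache = cache)
}

prop_matrix <- function(prop, t) {
  key <- sprintf("%.12g", t)
  P <- prop$cache[[key]]
  if (is.null(P)) {
    P <- as.matrix(Matrix::expm(prop$Q * t))
    prop$cache[[key]] <- P
  }
  P
}

# e^(Qt) %*% v
prop_apply <- function(prop, t, v) {
  if (t == 0) return(v)
  if (prop$use_eigen) {
    out <- prop$V %*% (exp(prop$values * t) * (prop$Vinv %*% v))
    out <- Re(out)
  } else {
    out <- prop_matrix(prop, t) %*% v
  }
  out <- as.numeric(out)
  out[out < 0] <- 0
  out
}

# t(e^(Qt)) %*% v  (adjoint transport, used by the ASR up pass)
prop_apply_t <- function(prop, t, v) {
  if (t == 0) return(v)
  if (prop$use_eigen) {
    out <- Re(Conj(t(prop$Vinv)) %*% (exp(prop$values * t) * (Conj(t(prop$V)) %*% v)))
  } else {
    out <- crossprod(prop_matrix(prop, t), v)
  }
  out <- as.numeric(out)
  out[out < 0] <- 0
  out
}

# Tree bookkeeping -----------------------------------------------------------

tree_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, length = tr$edge.length,
       ntip = ape::Ntip(tree), nnode = tree$Nnode,
       root = ape::Ntip(tree) + 1L)
}

tip_state_indices <- function(tree, tip_states, n_states) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != ape::Ntip(tree))
      stop("'tip_states' must be named by tip label or match the tip count")
    ts <- tip_states
  } else {
    miss <- setdiff(tree$tip.label, names(tip_states))
    if (length(miss)) stop("tips without states: ", paste(miss, collapse = ", "))
    ts <- tip_states[tree$tip.label]
  }
  ts <- as.integer(ts)
  if (any(is.na(ts)) || any(ts < 1L) || any(ts > n_states))
    stop("tip states must be state indices in 1..", n_states)
  ts
}

root_loglik <- function(D, root, lambda = NULL, E = NULL, condition = FALSE) {
  s <- sum(D)
  if (s <= 0) return(-Inf)
  prior <- switch(root,
                  flat = rep(1 / length(D), length(D)),
                  fitzjohn = D / s,
                  stop("unknown root handling: ", root))
  lik <- sum(prior * D)
  if (condition) {
    if (is.null(lambda) || is.null(E)) stop("survival conditioning needs lambda and E")
    denom <- sum(prior * lambda * (1 - E)^2)
    lik <- lik / denom
  }
  log(lik)
}

# Mk-n pruning likelihood ----------------------------------------------------

#' Mk-n log-likelihood by Felsenstein pruning
#'
#' Likelihood of tip states under the continuous-time Markov model with
#' generator `Q`: partial likelihood vectors are propagated rootward
#' along each branch as `e^(Qt) D_child` and multiplied elementwise at
#' internal nodes; the root sums over states under the chosen prior.
#' Partials are rescaled per node to avoid underflow (rescaling changes
#' only the decomposition, never the result).
#'
#' @param tree A `phylo`.
#' @param tip_states Named (by tip label) integer vector of state
#'   indices into `Q`'s state space, or unnamed in tip order.
#' @param Q Generator matrix (rows sum to zero).
#' @param root Root prior: `"flat"` (default) or `"fitzjohn"`
#'   (likelihood-weighted).
#' @param details If `TRUE`, return pruning internals (down partials
#'   and per-edge messages) for ancestral reconstruction.
#' @return The log-likelihood (or, with `details`, a list).
#' @export
mkn_loglik <- function(tree, tip_states, Q, root = c("flat", "fitzjohn"),
                       details = FALSE) {
  root <- match.arg(root)
  if (max(abs(Matrix::rowSums(Q))) > 1e-8) stop("Q rows must sum to zero")
  n <- nrow(Q)
  prop <- make_propagator(Q)
  po <- tree_postorder(tree)
  ts <- tip_state_indices(tree, tip_states, n)

  nn <- po$ntip + po$nnode
  D <- matrix(0, n, nn)
  for (i in seq_len(po$ntip)) D[ts[i], i] <- 1
  has_child <- logical(nn)
  M <- matrix(0, n, nrow(po$edge))  # per-edge message at parent end
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    m <- prop_apply(prop, po$length[e], D[, child])
    M[, e] <- m
    if (!has_child[parent]) {
      D[, parent] <- m; has_child[parent] <- TRUE
    } else D[, parent] <- D[, parent] * m
    sc <- sum(D[, parent])
    if (sc <= 0) return(if (details) list(loglik = -Inf) else -Inf)
    D[, parent] <- D[, parent] / sc
    M[, e] <- m / sc  # keep message consistent with rescaled partials
    logscale <- logscale + log(sc)
  }
  ll <- root_loglik(D[, po$root], root) + logscale
  if (!details) return(ll)
  list(loglik = ll, D = D, M = M, po = po, prop = prop, root = root, ts = ts)
}

# Constant-rate SSE helpers --------------------------------------------------
#
# With state-constant speciation rate lambda, extinction rate mu and
# sampling fraction f, the extinction probability E(t) is the same in
# every state: writing u = 1 - E, du/dt = r u - lambda u^2 with
# r = lambda - mu, a logistic equation with closed form. The D equation
# then separates into e^(Qt) transport times the state-independent
# scalar exp((lambda - mu) t) / g(t)^2 with
# g(t) = (r + lambda u0 (e^(rt) - 1)) / r. This exact reduction makes
# M0/M1/M4 likelihoods as cheap as Mk-n.

sse_const_E <- function(t, u0, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-12) 1 - u0 / (1 + lambda * u0 * t)
  else 1 - r * u0 * exp(r * t) / (r + lambda * u0 * (exp(r * t) - 1))
}

sse_const_logfactor <- function(t, u0, lambda, mu) {
  r <- lambda - mu
  if (lambda == 0) return(-mu * t)
  if (abs(r) < 1e-12) -2 * log1p(lambda * u0 * t)
  else r * t - 2 * log((r + lambda * u0 * (exp(r * t) - 1)) / r)
}

# MuSSE log-likelihood -------------------------------------------------------

#' Multi-state speciation-extinction (MuSSE-type) log-likelihood
#'
#' Along each branch the clade likelihoods `D_i` and extinction
#' probabilities `E_i` follow
#' \deqn{dE_i/dt = \mu_i - (\lambda_i + \mu_i) E_i + (QE)_i + \lambda_i E_i^2}
#' \deqn{dD_i/dt = -(\lambda_i + \mu_i) D_i + (QD)_i + 2 \lambda_i E_i D_i}
#' with tip conditions `D_i = f_i [i = observed]`, `E_i = 1 - f_i`, and
#' node joins `D_i <- lambda_i D_i^L D_i^R`. When `lambda`, `mu` and `f`
#' are state-constant and the tree is ultrametric, the exact
#' closed-form reduction (see the methods vignette) is used; otherwise
#' the ODEs are integrated per branch with a stiff-capable solver.
#'
#' @inheritParams mkn_loglik
#' @param lambda,mu Speciation and extinction rates: scalars or
#'   per-state vectors.
#' @param sampling_f Per-state sampling fractions (scalar or vector),
#'   default 1.
#' @param root Root handling: `"fitzjohn"` (default, likelihood-
#'   weighted) or `"flat"`.
#' @param condition_surv Condition the likelihood on survival of the
#'   two root lineages (off by default).
#' @param method `"auto"` picks the closed-form path when valid,
#'   `"ode"` forces numerical integration.
#' @param rtol,atol ODE tolerances.
#' @export
musse_loglik <- function(tree, tip_states, Q, lambda, mu, sampling_f = 1,
                         root = c("fitzjohn", "flat"), condition_surv = FALSE,
                         method = c("auto", "closed", "ode"),
                         rtol = 1e-8, atol = 1e-10, details = FALSE) {
  root <- match.arg(root)
  method <- match.arg(method)
  n <- nrow(Q)
  lambda <- rep_len(lambda, n); mu <- rep_len(mu, n)
  f <- rep_len(sampling_f, n)
  if (any(f < 0 | f > 1)) stop("sampling fractions must lie in [0, 1]")

  const <- length(unique(lambda)) == 1L && length(unique(mu)) == 1L &&
    length(unique(f)) == 1L
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ape::Ntip(tree))])
  ultra <- diff(range(depths[seq_len(ape::Ntip(tree))])) <= 1e-6 * max(height, 1)
  if (method == "closed" && !(const && ultra))
    stop("closed-form path needs state-constant lambda/mu/f and an ultrametric tree")
  use_closed <- method == "closed" || (method == "auto" && const && ultra)

  if (use_closed)
    musse_loglik_closed(tree, tip_states, Q, lambda[1], mu[1], f[1],
                        root, condition_surv, height, depths, details)
  else
    musse_loglik_ode(tree, tip_states, Q, lambda, mu, f,
                     root, condition_surv, rtol, atol, details)
}

musse_loglik_closed <- function(tree, tip_states, Q, lambda, mu, f,
                                root, condition_surv, height, depths, details) {
  n <- nrow(Q)
  prop <- make_propagator(Q)
  po <- tree_postorder(tree)
  ts <- tip_state_indices(tree, tip_states, n)
  nn <- po$ntip + po$nnode
  # time from the tips for every node (ultrametric)
  age <- height - depths
  u0_tip <- f  # u = 1 - E; at tips E = 1 - f

  D <- matrix(0, n, nn)
  for (i in seq_len(po$ntip)) D[ts[i], i] <- f
  has_child <- logical(nn)
  M <- matrix(0, n, nrow(po$edge))
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    t_e <- po$length[e]
    # E at the child end evolves from the tips below it: u at age[child]
    # equals the closed-form solution started from the tip value
    u_child <- 1 - sse_const_E(age[child], u0_tip, lambda, mu)
    m <- prop_apply(prop, t_e, D[, child])
    logscale <- logscale + sse_const_logfactor(t_e, u_child, lambda, mu)
    M[, e] <- m
    if (!has_child[parent]) {
      D[, parent] <- m; has_child[parent] <- TRUE
    } else {
      # speciation-event density per join; with lambda identically 0 the
      # model degenerates to pure character transport (the Mk limit)
      D[, parent] <- D[, parent] * m * (if (lambda > 0) lambda else 1)
    }
    sc <- sum(D[, parent])
    if (sc <= 0) return(if (details) list(loglik = -Inf) else -Inf)
    D[, parent] <- D[, parent] / sc
    M[, e] <- m / sc
    logscale <- logscale + log(sc)
  }
  E_root <- rep(sse_const_E(age[po$root], u0_tip, lambda, mu), n)
  ll <- root_loglik(D[, po$root], root, rep(lambda, n), E_root,
                    condition_surv) + logscale
  if (!details) return(ll)
  list(loglik = ll, D = D, M = M, po = po, prop = prop, root = root, ts = ts,
       closed = TRUE, lambda = rep(lambda, n), E_root = E_root)
}

sse_deriv <- function(t, state, parms) {
  n <- parms$n
  E <- state[seq_len(n)]; D <- state[n + seq_len(n)]
  QE <- as.numeric(parms$Q %*% E)
  QD <- as.numeric(parms$Q %*% D)
  dE <- parms$mu - (parms$lambda + parms$mu) * E + QE + parms$lambda * E^2
  dD <- -(parms$lambda + parms$mu) * D + QD + 2 * parms$lambda * E * D
  list(c(dE, dD))
}

sse_branch_ode <- function(Q, lambda, mu, E0, D0, t, rtol, atol) {
  n <- length(E0)
  if (t == 0) return(list(E = E0, D = D0))
  out <- deSolve::lsoda(c(E0, D0), c(0, t), sse_deriv,
                        parms = list(Q = Q, lambda = lambda, mu = mu, n = n),
                        rtol = rtol, atol = atol)
  if (nrow(out) < 2 || any(!is.finite(out[2, -1])))
    stop("SSE ODE integration failed on a branch of length ", t)
  fin <- unname(out[2, -1])
  list(E = pmin(pmax(fin[seq_len(n)], 0), 1), D = pmax(fin[n + seq_len(n)], 0))
}

musse_loglik_ode <- function(tree, tip_states, Q, lambda, mu, f,
                             root, condition_surv, rtol, atol, details) {
  n <- nrow(Q)
  po <- tree_postorder(tree)
  ts <- tip_state_indices(tree, tip_states, n)
  nn <- po$ntip + po$nnode
  D <- matrix(0, n, nn)
  E <- matrix(0, n, nn)
  for (i in seq_len(po$ntip)) {
    D[ts[i], i] <- f[ts[i]]
    E[, i] <- 1 - f
  }
  nchild <- integer(nn)
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    res <- sse_branch_ode(Q, lambda, mu, E[, child], D[, child],
                          po$length[e], rtol, atol)
    if (nchild[parent] == 0L) {
      D[, parent] <- res$D
      E[, parent] <- res$E
    } else {
      join <- if (all(lambda == 0)) 1 else lambda
      D[, parent] <- D[, parent] * res$D * join
      E[, parent] <- (E[, parent] * nchild[parent] + res$E) / (nchild[parent] + 1)
    }
    nchild[parent] <- nchild[parent] + 1L
    sc <- sum(D[, parent])
    if (sc <= 0) return(if (details) list(loglik = -Inf) else -Inf)
    D[, parent] <- D[, parent] / sc
    logscale <- logscale + log(sc)
  }
  ll <- root_loglik(D[, po$root], root, lambda, E[, po$root],
                    condition_surv) + logscale
  if (!details) return(ll)
  list(loglik = ll, D = D, E = E, po = po, root = root, ts = ts,
       closed = FALSE, lambda = lambda, mu = mu, Q = Q,
       rtol = rtol, atol = atol)
}
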
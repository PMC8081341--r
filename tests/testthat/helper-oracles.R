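# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/propagator code paths: likelihoods are exhaustive sums
# over internal-node state assignments, transition probabilities come from
# dense matrix exponentials, and ODE solutions from a plain fixed-step RK4.

# exhaustive Mk likelihood: sum over all internal-node state assignments
brute_force_mkn <- function(tree, tip_states, Q, prior = NULL) {
  n <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / n, n)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(as.matrix(Q) * tree$edge.length[e])))
  ts <- tip_states[tree$tip.label]
  total <- 0
  grid <- do.call(expand.grid, rep(list(seq_len(n)), nnode))
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(ts, as.integer(grid[g, ]))
    w <- prior[assign_[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      w <- w * P[[e]][assign_[tree$edge[e, 1]], assign_[tree$edge[e, 2]]]
    total <- total + w
  }
  log(total)
}

# exhaustive marginal posteriors for internal nodes under the Mk model
brute_force_asr <- function(tree, tip_states, Q, prior = NULL) {
  n <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / n, n)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(as.matrix(Q) * tree$edge.length[e])))
  ts <- tip_states[tree$tip.label]
  post <- matrix(0, nnode, n)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), nnode))
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(ts, as.integer(grid[g, ]))
    w <- prior[assign_[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      w <- w * P[[e]][assign_[tree$edge[e, 1]], assign_[tree$edge[e, 2]]]
    for (k in seq_len(nnode))
      post[k, assign_[ntip + k]] <- post[k, assign_[ntip + k]] + w
  }
  post / rowSums(post)
}

# random dense CTMC generator on n states
random_generator <- function(n) {
  Q <- matrix(stats::runif(n * n, 0, 0.5), n, n)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# random small tree with all tips assigned states
random_instance <- function(max_tips = 4, max_states = 6) {
  ntip <- sample(2:max_tips, 1)
  n <- sample(2:max_states, 1)
  tree <- ape::rtree(ntip)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 2)
  ts <- sample.int(n, ntip, replace = TRUE)
  names(ts) <- tree$tip.label
  list(tree = tree, tip_states = ts, Q = random_generator(n), n = n)
}

# fixed-step RK4 for the SSE D/E system, independent of deSolve
rk4_sse <- function(Q, lambda, mu, E0, D0, t, steps = 2000) {
  n <- length(E0)
  deriv <- function(s) {
    E <- s[seq_len(n)]; D <- s[n + seq_len(n)]
    QE <- as.numeric(Q %*% E); QD <- as.numeric(Q %*% D)
    c(mu - (lambda + mu) * E + QE + lambda * E^2,
      -(lambda + mu) * D + QD + 2 * lambda * E * D)
  }
  h <- t / steps
  s <- c(E0, D0)
  for (k in seq_len(steps)) {
    k1 <- deriv(s); k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2); k4 <- deriv(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(E = s[seq_len(n)], D = s[n + seq_len(n)])
}

# insert a degree-2 node halfway along the given edge of a binary tree
subdivide_edge <- function(tree, edge) {
  ntip <- ape::Ntip(tree)
  old_nn <- tree$Nnode
  new_node <- ntip + old_nn + 1L
  parent <- tree$edge[edge, 1]; child <- tree$edge[edge, 2]
  len <- tree$edge.length[edge]
  tree$edge[edge, ] <- c(parent, new_node)
  tree$edge <- rbind(tree$edge, c(new_node, child))
  tree$edge.length[edge] <- len / 2
  tree$edge.length <- c(tree$edge.length, len / 2)
  tree$Nnode <- old_nn + 1L
  tree
}

# minimal-cardinality coverage set by exhaustive subset search
brute_force_credible <- function(prob, coverage) {
  n <- length(prob)
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k)
    masses <- colSums(matrix(prob[combs], nrow = k))
    if (max(masses) >= coverage - 1e-12)
      return(list(size = k, mass = max(masses)))
  }
}

# literal reading of the 1% tail rule: accumulate ascending probabilities
# while the running total stays below alpha
brute_force_tail <- function(prob, alpha) {
  ord <- order(prob, seq_along(prob))
  out <- integer(0); cum <- 0
  for (i in ord) {
    cum <- cum + prob[i]
    if (cum >= alpha) break
    out <- c(out, i)
  }
  out
}

# fake ASR object for detector tests
fake_asr <- function(tree, space, node_modes, tip_states) {
  summ <- data.frame(node = ape::Ntip(tree) + seq_len(tree$Nnode),
                     mode_x = node_modes[, 1], mode_y = node_modes[, 2])
  structure(list(summary = summ, tree = tree, space = space,
                 tip_states = tip_states), class = "karyo_asr")
}
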
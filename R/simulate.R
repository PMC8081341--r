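#' Simulate karyotype evolution along a tree
#'
#' Forward (Gillespie) simulation of the continuous-time karyotype walk
#' down a fixed phylogeny: starting from the root state, each branch is
#' traversed with exponential waiting times at rate `-q_ii` and jumps
#' chosen proportionally to the off-diagonal rates of `Q`. The character
#' does not feed back on the tree (no state-dependent diversification in
#' the simulation). Traversal is preorder, so a given seed reproduces
#' the full realization exactly.
#'
#' @param tree A `phylo` with branch lengths.
#' @param Q Generator from [karyo_rate_matrix()] (space attached).
#' @param root_state Root karyotype, either a state index or a
#'   length-2 vector `c(x, y)`.
#' @param seed Optional integer seed (set once for the whole run).
#' @param events If `TRUE`, also return the full event log.
#' @return A named integer vector of tip state indices (attribute
#'   `space`). Attribute `node_states` holds the realized state at every
#'   node (tips then internal, ape numbering); with `events = TRUE`,
#'   attribute `events` is a data frame (branch, time, from, to).
#' @export
sim_karyotype_tips <- function(tree, Q, root_state, seed = NULL, events = FALSE) {
  space <- attr(Q, "space")
  if (length(root_state) == 2L) root_state <- state_index(space, root_state[1], root_state[2])
  if (is.na(root_state) || root_state < 1L || root_state > nrow(space))
    stop("root state is outside the state space")
  with_seed(seed, sim_karyotype_tips_impl(tree, Q, space, root_state, events))
}

sim_karyotype_tips_impl <- function(tree, Q, space, root_state, events) {
  n <- nrow(Q)
  # adjacency lists: targets and rates per state
  coo <- Matrix::summary(Q)
  coo <- coo[coo$i != coo$j & coo$x > 0, , drop = FALSE]
  targets <- split(coo$j, factor(coo$i, levels = seq_len(n)))
  rates <- split(coo$x, factor(coo$i, levels = seq_len(n)))
  totals <- vapply(rates, function(r) sum(r), 0)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  node_state <- integer(ntip + nnode)
  root <- ntip + 1L
  node_state[root] <- as.integer(root_state)

  ord <- tree$edge[reorder_edges_preorder(tree), , drop = FALSE]
  len <- tree$edge.length[reorder_edges_preorder(tree)]
  ev <- if (events) vector("list", nrow(ord)) else NULL

  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1L]; child <- ord[e, 2L]
    s <- node_state[parent]
    t_left <- len[e]; t_at <- 0
    log_e <- NULL
    repeat {
      tot <- totals[s]
      if (tot <= 0) break
      w <- stats::rexp(1, tot)
      if (w > t_left) break
      t_left <- t_left - w; t_at <- t_at + w
      r <- rates[[s]]
      s_new <- targets[[s]][sample.int(length(r), 1L, prob = r)]
      if (events)
        log_e <- rbind(log_e, data.frame(branch = e, time = t_at,
                                         from = s, to = s_new))
      s <- s_new
    }
    node_state[child] <- s
    if (events) ev[[e]] <- log_e
  }

  tips <- node_state[seq_len(ntip)]
  names(tips) <- tree$tip.label
  attr(tips, "space") <- space
  attr(tips, "node_states") <- node_state
  attr(tips, "edge_order") <- reorder_edges_preorder(tree)
  if (events) attr(tips, "events") <- do.call(rbind, ev)
  tips
}

# preorder edge permutation (root-to-tip), cached computation
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tr$edge[, 1], tr$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Draw random transition-rate coefficients
#'
#' Draws `k1..k4` independently as `10^u` with `u ~ Uniform(-4, -1)`,
#' the log-uniform design used for parameter-recovery simulation
#' studies.
#'
#' @param seed Optional integer seed.
#' @param lambda,mu Speciation/extinction rates to attach (default 0).
#' @return A `karyo_rates` object.
#' @export
random_rates <- function(seed = NULL, lambda = 0, mu = 0) {
  k <- with_seed(seed, 10^stats::runif(4, -4, -1))
  karyo_rates(k[1], k[2], k[3], k[4], lambda = lambda, mu = mu)
}

#' Simulate a birth-death tree fixture
#'
#' Ultrametric tree with a fixed number of extant tips, conditioned on
#' survival, via [ape::rphylo()]. Used as a synthetic stand-in for
#' empirical time-calibrated phylogenies in tests and simulation
#' studies.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates (`birth > death`).
#' @param seed Optional integer seed.
#' @return A `phylo`.
#' @export
sim_bd_tree <- function(n_tips, birth, death = 0, seed = NULL) {
  if (n_tips < 2) stop("'n_tips' must be >= 2")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  with_seed(seed, ape::rphylo(n_tips, birth, death))
}
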
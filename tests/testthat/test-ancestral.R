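mk_fit_stub <- function(tree, tips, rates, y_max, method = "mkn",
                        root = "flat") {
  # a karyo_fit at fixed parameters (no optimization), for ASR testing
  sp <- karyo_states(y_max)
  structure(list(model = "M0", method = method, rates = rates,
                 estimates = unlist(rates[1:4]),
                 loglik = NA_real_, npar = 4L, converged = TRUE,
                 root = root, condition_surv = FALSE, space = sp,
                 y_max = y_max, focal = NULL, focal_idx = integer(0),
                 sampling_f = rep(1, nrow(sp)), tree = tree,
                 tip_states = tips),
            class = "karyo_fit")
}

test_that("near-static tips pin the ancestral karyotype", {
  sp <- karyo_states(30)
  tree <- sim_bd_tree(8, 0.3, 0, seed = 1)
  tips <- stats::setNames(rep(state_index(sp, 24, 24), 8), tree$tip.label)
  fit <- mk_fit_stub(tree, tips, karyo_rates(1e-7, 1e-7, 1e-7, 1e-7), 30)
  asr <- marginal_asr(fit)
  expect_equal(asr$summary$mode_x[1], 24)
  expect_equal(asr$summary$mode_y[1], 24)
  expect_gt(asr$prob[1, state_index(sp, 24, 24)], 0.999)
  expect_equal(rowSums(asr$prob), rep(1, nrow(asr$prob)), tolerance = 1e-10)
})

test_that("marginal reconstruction matches exhaustive posterior enumeration", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  sp1 <- karyo_states(1)
  rates <- karyo_rates(0, 0, 0.05, 0.09)
  Q1 <- karyo_rate_matrix(sp1, rates)
  ts <- c(A = 1L, B = 2L, C = 1L)
  fit <- mk_fit_stub(tr, ts, rates, 1)
  asr <- marginal_asr(fit)
  ref <- brute_force_asr(tr, ts, as.matrix(Q1))
  expect_equal(asr$prob, ref, tolerance = 1e-10, ignore_attr = TRUE)

  # larger random instance, 4 tips, 5 states
  set.seed(33)
  tr4 <- ape::rtree(4)
  tr4$edge.length <- stats::runif(nrow(tr4$edge), 0.2, 1.5)
  sp2 <- karyo_states(2)
  rates2 <- karyo_rates(0.2, 0.15, 0.3, 0.25)
  Q2 <- karyo_rate_matrix(sp2, rates2)
  ts4 <- stats::setNames(sample.int(5, 4, replace = TRUE), tr4$tip.label)
  fit4 <- mk_fit_stub(tr4, ts4, rates2, 2)
  asr4 <- marginal_asr(fit4)
  ref4 <- brute_force_asr(tr4, ts4, as.matrix(Q2))
  expect_equal(asr4$prob, ref4, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("SSE reconstruction reduces to the Mk reconstruction without diversification", {
  sp <- karyo_states(2)
  tree <- sim_bd_tree(10, 0.3, 0, seed = 2)
  rates <- karyo_rates(0.05, 0.04, 0.06, 0.05)
  Q <- karyo_rate_matrix(sp, rates)
  tips <- sim_karyotype_tips(tree, Q, c(3, 2), seed = 3)
  fit_mk <- mk_fit_stub(tree, tips, rates, 2, method = "mkn", root = "flat")
  fit_sse <- mk_fit_stub(tree, tips, rates, 2, method = "musse", root = "flat")
  a1 <- marginal_asr(fit_mk)
  a2 <- marginal_asr(fit_sse)
  expect_equal(a1$prob, a2$prob, tolerance = 1e-6)
})

test_that("state-dependent reconstruction matches pinned-node likelihoods", {
  # tiny M2-like setting: 2 states, focal state with distinct lambda/mu;
  # oracle pins each node state and recomputes the full ODE likelihood
  sp <- karyo_states(1)
  rates <- karyo_rates(0, 0, 0.03, 0.05,
                       lambda = c(focal = 0.35, other = 0.15),
                       mu = c(focal = 0.01, other = 0.08))
  Q <- karyo_rate_matrix(sp, rates)
  tree <- read_newick("((A:1,B:1):0.7,(C:1.2,D:1.2):0.5);",
                      warn_ultrametric = FALSE)
  ts <- c(A = 1L, B = 2L, C = 2L, D = 1L)
  fit <- mk_fit_stub(tree, ts, rates, 1, method = "musse", root = "flat")
  fit$focal_idx <- 1L
  asr <- marginal_asr(fit)

  lambda <- c(0.35, 0.15); mu <- c(0.01, 0.08)
  ntip <- 4L
  # pinned oracle: enumerate both internal non-root nodes jointly with the
  # root, propagating each branch with the independent RK4 integrator
  P_of <- function(E0, t) {
    vapply(1:2, function(k) {
      D0 <- c(0, 0); D0[k] <- 1
      rk4_sse(as.matrix(Q), lambda, mu, E0, D0, t, steps = 3000)$D
    }, numeric(2))
  }
  E_tip <- c(0, 0)
  E1 <- rk4_sse(as.matrix(Q), lambda, mu, E_tip, c(1, 0), 1, steps = 3000)$E
  P_A <- P_of(E_tip, 1); P_C <- P_of(E_tip, 1.2)
  E_n2 <- rk4_sse(as.matrix(Q), lambda, mu, E1, c(1, 0), 0.7, steps = 3000)$E
  P_n2 <- P_of(E1, 0.7)
  E1c <- rk4_sse(as.matrix(Q), lambda, mu, E_tip, c(1, 0), 1.2, steps = 3000)$E
  P_n3 <- P_of(E1c, 0.5)
  post <- matrix(0, 3, 2)  # root, node(AB), node(CD)
  # Phi[top, bottom]: clade likelihood at the branch top given the bottom
  for (r in 1:2) for (m2 in 1:2) for (m3 in 1:2) {
    w <- 0.5 * lambda[r] *
      (lambda[m2] * P_A[m2, ts[["A"]]] * P_A[m2, ts[["B"]]]) * P_n2[r, m2] *
      (lambda[m3] * P_C[m3, ts[["C"]]] * P_C[m3, ts[["D"]]]) * P_n3[r, m3]
    post[1, r] <- post[1, r] + w
    post[2, m2] <- post[2, m2] + w
    post[3, m3] <- post[3, m3] + w
  }
  post <- post / rowSums(post)
  expect_equal(asr$prob, post, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pulling a tip toward a larger karyotype raises its parent's mean", {
  sp <- karyo_states(8)
  tree <- sim_bd_tree(6, 0.3, 0, seed = 4)
  rates <- karyo_rates(0.01, 0.01, 0.01, 0.01)
  base <- stats::setNames(rep(state_index(sp, 6, 4), 6), tree$tip.label)
  fit0 <- mk_fit_stub(tree, base, rates, 8)
  a0 <- marginal_asr(fit0)
  tip1_parent <- tree$edge[tree$edge[, 2] == 1L, 1L]
  row0 <- which(a0$summary$node == tip1_parent)
  # move the tip along the arm axis only: parent mean x must rise
  moved_x <- base
  moved_x[tree$tip.label[1]] <- state_index(sp, 8, 4)
  a_x <- marginal_asr(mk_fit_stub(tree, moved_x, rates, 8))
  expect_gt(a_x$summary$mean_x[row0], a0$summary$mean_x[row0])
  # move it along the chromosome axis only: parent mean y must rise
  moved_y <- base
  moved_y[tree$tip.label[1]] <- state_index(sp, 6, 6)
  a_y <- marginal_asr(mk_fit_stub(tree, moved_y, rates, 8))
  expect_gt(a_y$summary$mean_y[row0], a0$summary$mean_y[row0])
})

test_that("unconverged fits are refused unless forced", {
  fx_sp <- karyo_states(2)
  tree <- sim_bd_tree(5, 0.3, 0, seed = 5)
  tips <- stats::setNames(rep(1L, 5), tree$tip.label)
  fit <- mk_fit_stub(tree, tips, karyo_rates(.01, .01, .01, .01), 2)
  fit$converged <- FALSE
  expect_error(marginal_asr(fit), "converge")
  expect_s3_class(marginal_asr(fit, force = TRUE), "karyo_asr")
})

test_that("credible ranges use the smallest high-probability set", {
  sp <- karyo_states(30)
  p <- numeric(nrow(sp)); p[state_index(sp, 24, 24)] <- 1
  r <- range_summary(p, sp)
  expect_equal(unname(r), c(24, 24, 24, 24), ignore_attr = TRUE)

  p2 <- numeric(nrow(sp))
  p2[state_index(sp, c(24, 25, 26), c(24, 24, 25))] <- 1 / 3
  r2 <- range_summary(p2, sp, coverage = 0.95)
  expect_equal(unname(r2), c(24, 25, 24, 26), ignore_attr = TRUE)

  # minimality against exhaustive subset search on small vectors
  sp_small <- karyo_states(2)  # 5 states
  set.seed(50)
  for (rep in 1:20) {
    p <- stats::runif(5); p <- p / sum(p)
    ord <- order(-p, seq_along(p))
    k <- which(cumsum(p[ord]) >= 0.95 - 1e-12)[1]
    ref <- brute_force_credible(p, 0.95)
    expect_equal(k, ref$size)
    expect_equal(sum(p[ord[seq_len(k)]]), ref$mass, tolerance = 1e-12)
  }

  # marginal-quantile alternative is labelled and wider or equal
  p3 <- numeric(nrow(sp)); i <- state_index(sp, c(24, 30), c(24, 25))
  p3[i] <- c(0.97, 0.03)
  rm_ <- range_summary(p3, sp, method = "marginal")
  expect_equal(attr(rm_, "method"), "marginal")
})

test_that("the 1.4-fold rule flags only joint chromosome and arm doubling", {
  sp <- karyo_states(25)
  tree <- read_newick("((A:1,B:1):1,C:2);")
  # root mode (12,8); internal node above A,B carries the candidate change
  tipA <- state_index(sp, 24, 16); tipB <- state_index(sp, 24, 16)
  tipC <- state_index(sp, 12, 8)
  cases <- list(
    list(child = c(24, 16), expect = TRUE),    # ratios 2.0 / 2.0
    list(child = c(16, 11), expect = FALSE),   # y ratio 1.375
    list(child = c(18, 10), expect = FALSE))   # x 1.5 but y 1.25
  for (cs in cases) {
    asr <- fake_asr(tree, sp,
                    node_modes = rbind(c(12, 8), cs$child),
                    tip_states = c(A = tipA, B = tipB, C = tipC))
    d <- detect_polyploidization(asr)
    internal_edge <- which(d$child == ape::Ntip(tree) + 2L)
    expect_identical(d$polyploidization[internal_edge], cs$expect)
  }
})
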
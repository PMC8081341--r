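test_that("pruning handles the no-change and impossible-change limits", {
  cherry <- read_newick("(A:1,B:1);", warn_ultrametric = FALSE)
  n <- 5
  Q0 <- matrix(0, n, n)
  expect_equal(mkn_loglik(cherry, c(A = 3L, B = 3L), Q0), log(1 / n))
  expect_equal(mkn_loglik(cherry, c(A = 3L, B = 4L), Q0), -Inf)
})

test_that("pruning equals exhaustive summation over internal states", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  sp1 <- karyo_states(1)
  Q1 <- as.matrix(karyo_rate_matrix(sp1, karyo_rates(0.05, 0.05, 0.05, 0.05)))
  ts <- c(A = 1L, B = 2L, C = 1L)
  expect_equal(mkn_loglik(tr, ts, Q1), brute_force_mkn(tr, ts, Q1),
               tolerance = 1e-10)

  set.seed(20)
  for (rep in 1:30) {
    inst <- random_instance()
    expect_equal(mkn_loglik(inst$tree, inst$tip_states, inst$Q),
                 brute_force_mkn(inst$tree, inst$tip_states, inst$Q),
                 tolerance = 1e-10)
  }
})

test_that("errors on unbound tips and non-generator input", {
  cherry <- read_newick("(A:1,B:1);", warn_ultrametric = FALSE)
  Q <- random_generator(3)
  expect_error(mkn_loglik(cherry, c(A = 1L), Q), "without states")
  expect_error(mkn_loglik(cherry, c(A = 1L, B = 9L), Q), "state indices")
  expect_error(mkn_loglik(cherry, c(A = 1L, B = 2L), Q + 1), "sum to zero")
})

test_that("SSE likelihood with no diversification reduces to the Mk transport", {
  sp <- karyo_states(3)
  Q <- karyo_rate_matrix(sp, karyo_rates(0.02, 0.03, 0.04, 0.05))
  tree <- sim_bd_tree(12, 0.3, 0, seed = 6)
  tips <- sim_karyotype_tips(tree, Q, c(3, 2), seed = 7)
  ll_mk <- mkn_loglik(tree, tips, Q, root = "flat")
  ll_closed <- musse_loglik(tree, tips, Q, 0, 0, root = "flat")
  ll_ode <- musse_loglik(tree, tips, Q, 0, 0, root = "flat", method = "ode")
  expect_equal(ll_closed, ll_mk, tolerance = 1e-6)
  expect_equal(ll_ode, ll_mk, tolerance = 1e-6)
})

test_that("closed-form constant-rate SSE path agrees with the ODE integrator", {
  sp <- karyo_states(3)
  Q <- karyo_rate_matrix(sp, karyo_rates(0.02, 0.03, 0.04, 0.05))
  tree <- sim_bd_tree(10, 0.3, 0.1, seed = 8)
  tips <- sim_karyotype_tips(tree, Q, c(3, 2), seed = 9)
  for (f in c(1, 0.6)) {
    ll_c <- musse_loglik(tree, tips, Q, 0.3, 0.1, sampling_f = f,
                         method = "closed")
    ll_o <- musse_loglik(tree, tips, Q, 0.3, 0.1, sampling_f = f,
                         method = "ode")
    expect_equal(ll_c, ll_o, tolerance = 1e-6)
  }
  # survival conditioning shifts both paths identically
  ll_cs <- musse_loglik(tree, tips, Q, 0.3, 0.1, condition_surv = TRUE,
                        method = "closed")
  ll_os <- musse_loglik(tree, tips, Q, 0.3, 0.1, condition_surv = TRUE,
                        method = "ode")
  expect_equal(ll_cs, ll_os, tolerance = 1e-6)
})

test_that("single-branch D/E profiles match an independent RK4 integration", {
  sp <- karyo_states(2)  # 5 states
  Q <- as.matrix(karyo_rate_matrix(sp, karyo_rates(0.1, 0.2, 0.15, 0.25)))
  n <- nrow(Q)
  lambda <- seq(0.1, 0.3, length.out = n)
  mu <- seq(0.02, 0.1, length.out = n)
  f <- 0.8
  D0 <- numeric(n); D0[3] <- f
  E0 <- rep(1 - f, n)
  ours <- karyograph:::sse_branch_ode(Q, lambda, mu, E0, D0, t = 2,
                                      rtol = 1e-10, atol = 1e-12)
  ref <- rk4_sse(Q, lambda, mu, E0, D0, t = 2, steps = 4000)
  expect_equal(ours$E, ref$E, tolerance = 1e-8)
  expect_equal(ours$D, ref$D, tolerance = 1e-8)
})

test_that("likelihood is invariant to subdividing a branch", {
  sp <- karyo_states(2)
  Q <- karyo_rate_matrix(sp, karyo_rates(0.05, 0.05, 0.08, 0.06))
  tree <- sim_bd_tree(8, 0.3, 0, seed = 10)
  tips <- sim_karyotype_tips(tree, Q, c(2, 2), seed = 11)
  ll <- musse_loglik(tree, tips, Q, 0.3, 0.05)
  for (edge in c(1, 4)) {
    tree2 <- subdivide_edge(tree, edge)
    ll2 <- musse_loglik(tree2, tips, Q, 0.3, 0.05)
    expect_equal(ll2, ll, tolerance = 1e-8)
  }
  ll_mk <- mkn_loglik(tree, tips, Q)
  expect_equal(mkn_loglik(subdivide_edge(tree, 2), tips, Q), ll_mk,
               tolerance = 1e-8)
})

test_that("state-dependent diversification moves the likelihood as expected", {
  sp <- karyo_states(1)  # 2 states
  Q <- karyo_rate_matrix(sp, karyo_rates(0, 0, 0.02, 0.02))
  tree <- sim_bd_tree(15, 0.25, 0, seed = 12)
  tips <- stats::setNames(rep(c(1L, 2L), length.out = 15), tree$tip.label)
  lam_hi1 <- musse_loglik(tree, tips, Q, c(0.4, 0.1), c(0.01, 0.01))
  lam_hi2 <- musse_loglik(tree, tips, Q, c(0.1, 0.4), c(0.01, 0.01))
  # mixed tips: both orderings give finite, different likelihoods
  expect_true(is.finite(lam_hi1) && is.finite(lam_hi2))
  expect_false(isTRUE(all.equal(lam_hi1, lam_hi2)))
})
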
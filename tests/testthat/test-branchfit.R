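fitted_scale_Q <- function() {
  # rate coefficients on the order of empirical fish estimates
  sp <- karyo_states(8)
  karyo_rate_matrix(sp, karyo_rates(1.48e-4, 2.45e-3, 4.13e-3, 2.68e-2))
}

test_that("transition probabilities are stochastic rows with piecewise evaluation", {
  Q <- fitted_scale_Q()
  i <- state_index(attr(Q, "space"), 6, 4)
  p0 <- transition_probability(Q, i, 0)
  expect_equal(p0[i], 1)
  expect_equal(sum(p0), 1)
  for (t in c(0.5, 3, 9.9, 50, 14000))
    expect_equal(sum(transition_probability(Q, i, t)), 1, tolerance = 1e-10)
  expect_true(all(is.na(transition_probability(Q, i, -0.5))))
  expect_true(all(is.na(transition_probability(Q, i, 15001))))
})

test_that("degree-170 Taylor row evaluation matches the exact exponential below t = 10", {
  Q <- fitted_scale_Q()
  sp <- attr(Q, "space")
  starts <- state_index(sp, c(6, 8, 12), c(4, 8, 8))
  for (i in starts) for (t in c(0.01, 0.5, 2, 5, 8, 9.99)) {
    pt <- transition_probability(Q, i, t, method = "taylor")
    pe <- transition_probability(Q, i, t, method = "expm")
    expect_lt(max(abs(pt - pe)), 1e-9)
  }
  # a second, faster-evolving generator
  sp2 <- karyo_states(5)
  Q2 <- karyo_rate_matrix(sp2, karyo_rates(0.02, 0.05, 0.08, 0.04))
  for (t in c(1, 9.5)) {
    pt <- transition_probability(Q2, 5, t, method = "taylor")
    pe <- transition_probability(Q2, 5, t, method = "expm")
    expect_lt(max(abs(pt - pe)), 1e-9)
  }
})

test_that("fitted branch lengths maximize the transition probability", {
  # identical endpoints define t_f = 0
  Q <- fitted_scale_Q()
  expect_identical(as.numeric(fit_branch_length(Q, 12, 12)), 0)

  # two-state chain: attained probability matches a dense grid scan
  sp1 <- karyo_states(1)
  Q1 <- karyo_rate_matrix(sp1, karyo_rates(0, 0, 0.03, 0.07))
  tf <- fit_branch_length(Q1, 1, 2)
  grid <- exp(seq(log(0.01), log(15000), length.out = 4000))
  pgrid <- vapply(grid, function(t)
    as.matrix(Matrix::expm(as.matrix(Q1) * t))[1, 2], 0)
  p_at_tf <- transition_probability(Q1, 1, as.numeric(tf))[2]
  expect_equal(signif(p_at_tf, 3), signif(max(pgrid), 3))

  # interior maximum: scaling Q scales t_f inversely
  sp <- attr(Q, "space")
  i <- state_index(sp, 8, 8); j <- state_index(sp, 9, 8)
  tf1 <- as.numeric(fit_branch_length(Q, i, j))
  Qc <- Q * 4; attr(Qc, "space") <- sp
  tf4 <- as.numeric(fit_branch_length(Qc, i, j))
  expect_equal(tf4, tf1 / 4, tolerance = 1e-3)
})

test_that("the 1% tail rule selects the strict low-probability prefix", {
  expect_equal(tail_region(c(0.005, 0.004, 0.991)), c(2L, 1L))
  expect_length(tail_region(rep(0.25, 4)), 0)
  set.seed(60)
  for (rep in 1:25) {
    p <- stats::rexp(20); p <- p / sum(p)
    expect_equal(tail_region(p), brute_force_tail(p, 0.01))
  }
})

test_that("branch classification follows the four-way decision tree", {
  Q <- fitted_scale_Q()
  i <- state_index(attr(Q, "space"), 6, 4)
  expect_equal(classify_branch(Q, i, i, 50), "Expected")

  # drift chain on y_max = 2 with strong fission/A-M bias: a transient
  # state is likely only at intermediate durations
  spc <- karyo_states(2)
  Qc <- karyo_rate_matrix(spc, karyo_rates(1e-4, 0.05, 0.05, 1e-4))
  ic <- state_index(spc, 1, 1); jc <- state_index(spc, 2, 1)
  tfc <- as.numeric(fit_branch_length(Qc, ic, jc))
  # short true branch: j improbable at t_g but likely at the (longer) t_f
  expect_true(jc %in% tail_region(transition_probability(Qc, ic, 0.05)))
  expect_false(jc %in% tail_region(transition_probability(Qc, ic, tfc)))
  expect_gt(tfc, 0.05)
  expect_equal(classify_branch(Qc, ic, jc, 0.05), "Rapid")
  # very long true branch: the transient is gone at t_g, kept at t_f < t_g
  expect_true(jc %in% tail_region(transition_probability(Qc, ic, 8000)))
  expect_equal(classify_branch(Qc, ic, jc, 8000), "Conservative")
  # against-the-drift target is in the tail at every duration: Unusual
  iu <- state_index(spc, 4, 2); ju <- state_index(spc, 1, 1)
  tfu <- as.numeric(fit_branch_length(Qc, iu, ju))
  expect_true(ju %in% tail_region(transition_probability(Qc, iu, 100)))
  expect_true(ju %in% tail_region(transition_probability(Qc, iu, tfu)))
  expect_equal(classify_branch(Qc, iu, ju, 100), "Unusual")
})

test_that("model-true branches classify overwhelmingly as Expected", {
  Q <- fitted_scale_Q()
  sp <- attr(Q, "space")
  tree <- sim_bd_tree(120, 0.1, 0, seed = 30)
  tips <- sim_karyotype_tips(tree, Q, c(6, 4), seed = 31)
  ns <- attr(tips, "node_states")
  cats <- vapply(seq_len(nrow(tree$edge)), function(e) {
    classify_branch(Q, ns[tree$edge[e, 1]], ns[tree$edge[e, 2]],
                    tree$edge.length[e])
  }, "")
  expect_gte(mean(cats == "Expected"), 0.95)
})

test_that("branch annotation reports transitions, fitted lengths and categories", {
  sp <- karyo_states(4)
  rates <- karyo_rates(0.02, 0.02, 0.03, 0.03)
  Q <- karyo_rate_matrix(sp, rates)
  tree <- sim_bd_tree(12, 0.2, 0, seed = 32)
  tips <- sim_karyotype_tips(tree, Q, c(4, 3), seed = 33)
  fit <- structure(list(model = "M0", method = "mkn", rates = rates,
                        estimates = unlist(rates[1:4]), loglik = NA_real_,
                        npar = 4L, converged = TRUE, root = "flat",
                        condition_surv = FALSE, space = sp, y_max = 4,
                        focal = NULL, focal_idx = integer(0),
                        sampling_f = rep(1, nrow(sp)),
                        tree = tree, tip_states = tips),
                   class = "karyo_fit")
  asr <- marginal_asr(fit)
  ann <- annotate_branches(fit, asr)
  expect_equal(nrow(ann), nrow(tree$edge))
  expect_true(all(ann$category %in%
                    c("Expected", "Conservative", "Rapid", "Unusual")))
  same <- ann$anc_x == ann$des_x & ann$anc_y == ann$des_y
  expect_true(all(ann$t_f[same] == 0))
  expect_true(all(ann$category[same] == "Expected"))
  expect_equal(sum(ann$is_terminal), ape::Ntip(tree))
  expect_true(all(ann$t_g == tree$edge.length))
})
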
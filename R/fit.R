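# Model ladder ---------------------------------------------------------------
#
# M0  : k1..k4 + constant lambda, mu                  (6 free parameters)
# M0' : M0 likelihood but with the M2 group sampling fractions (for the
#       nested comparison against M2)                 (6)
# M1  : K_i constrained to 1 (k4 = k3)                (5)
# M2  : k1..k4 + (lambda, mu) differing between a focal karyotype set
#       and all other karyotypes                      (8)
# M3  : M2 with k4 = k3                               (7)
# M4  : M0 plus a polyploidization rate k5            (7)

model_params <- list(
  M0      = c("k1", "k2", "k3", "k4", "lambda", "mu"),
  M0prime = c("k1", "k2", "k3", "k4", "lambda", "mu"),
  M1      = c("k1", "k2", "k3", "lambda", "mu"),
  M2      = c("k1", "k2", "k3", "k4", "lambda_m", "mu_m", "lambda_o", "mu_o"),
  M3      = c("k1", "k2", "k3", "lambda_m", "mu_m", "lambda_o", "mu_o"),
  M4      = c("k1", "k2", "k3", "k4", "k5", "lambda", "mu")
)

# registered nestings (null, full) for likelihood-ratio tests
model_nestings <- rbind(
  c("M1", "M0"), c("M3", "M2"), c("M0prime", "M2"), c("M1", "M3"),
  c("M0", "M4")
)

model_grouped <- c(M0 = FALSE, M0prime = FALSE, M1 = FALSE,
                   M2 = TRUE, M3 = TRUE, M4 = FALSE)

params_to_rates <- function(model, p) {
  k4 <- if ("k4" %in% names(p)) p[["k4"]] else p[["k3"]]
  k5 <- if ("k5" %in% names(p)) p[["k5"]] else 0
  if (model_grouped[[model]]) {
    lambda <- c(focal = p[["lambda_m"]], other = p[["lambda_o"]])
    mu <- c(focal = p[["mu_m"]], other = p[["mu_o"]])
  } else {
    lambda <- p[["lambda"]]; mu <- p[["mu"]]
  }
  karyo_rates(p[["k1"]], p[["k2"]], p[["k3"]], k4, k5 = k5,
              lambda = lambda, mu = mu)
}

state_vectors <- function(space, rates, focal_idx) {
  n <- nrow(space)
  if (length(rates$lambda) == 2L) {
    lambda <- rep(rates$lambda[["other"]], n)
    mu <- rep(rates$mu[["other"]], n)
    lambda[focal_idx] <- rates$lambda[["focal"]]
    mu[focal_idx] <- rates$mu[["focal"]]
  } else {
    lambda <- rep(rates$lambda, n); mu <- rep(rates$mu, n)
  }
  list(lambda = lambda, mu = mu)
}

#' Average sampling fractions per diversification group
#'
#' The sampling fraction of a state is the number of species mapped on
#' the phylogeny divided by the number of species karyotyped in that
#' state; states sharing speciation/extinction rates in the model are
#' then summarized by the arithmetic mean of their per-state fractions.
#'
#' @param n_on_tree,n_karyotyped Per-state counts (equal length;
#'   `n_on_tree <= n_karyotyped` elementwise).
#' @param group Group label per state (factor/character); states with
#'   `n_karyotyped = 0` are excluded from the mean, and a group with no
#'   karyotyped state is an error.
#' @return Named numeric vector of per-group fractions.
#' @examples
#' sampling_fractions(c(2, 4), c(4, 4), c("g", "g"))  # 0.75
#' @export
sampling_fractions <- function(n_on_tree, n_karyotyped, group) {
  stopifnot(length(n_on_tree) == length(n_karyotyped),
            length(group) == length(n_on_tree))
  if (any(n_on_tree < 0) || any(n_karyotyped < 0) ||
      any(n_on_tree > n_karyotyped))
    stop("need 0 <= n_on_tree <= n_karyotyped per state")
  has <- n_karyotyped > 0
  vapply(split(seq_along(group), group), function(i) {
    i <- i[has[i]]
    if (!length(i)) stop("group with no karyotyped state: fraction undefined")
    mean(n_on_tree[i] / n_karyotyped[i])
  }, 0)
}

#' Fit a karyotype-evolution model by maximum likelihood
#'
#' Maximizes the Mk-n or MuSSE-type log-likelihood of tip karyotypes on
#' a time-calibrated tree over the free parameters of one of the models
#' M0-M4 (see the model ladder in the package vignette). Optimization
#' is bounded quasi-Newton (`L-BFGS-B`) on log10 parameters with
#' multiple starts: the 0.1 prior, a Yule-informed heuristic, and
#' random draws.
#'
#' @param tree A rooted, time-calibrated `phylo`.
#' @param tip_states Named integer vector of state indices (see
#'   [attach_tip_states()]), or a data frame with columns
#'   `species`, `x`, `y`.
#' @param model One of `"M0"`, `"M0prime"`, `"M1"`, `"M2"`, `"M3"`,
#'   `"M4"`.
#' @param y_max Maximum chromosome number of the state space.
#' @param method `"musse"` (default; includes diversification) or
#'   `"mkn"` (pure character model; only the k parameters are free).
#' @param focal Focal karyotypes receiving `(lambda_m, mu_m)` under
#'   M2/M3: a two-column matrix or data frame of `(x, y)` rows.
#' @param sampling_f Per-group sampling fractions
#'   `c(focal = ..., other = ...)` for M2/M3/M0prime, or a scalar; the
#'   default 1 applies no correction (none is applied for M0/M1/M4).
#' @param root Root handling passed to the likelihood ([musse_loglik()]
#'   default `"fitzjohn"`, [mkn_loglik()] default `"flat"`).
#' @param condition_surv Condition on survival (MuSSE only).
#' @param n_starts Number of optimizer starts (>= 1).
#' @param lower,upper log10 box bounds for all free parameters.
#' @param seed Seed for the random starts.
#' @param control Passed to [stats::optim()].
#' @return An object of class `karyo_fit` with `print`, `summary`,
#'   `coef`, `logLik`, `simulate` and `anova` methods.
#' @export
fit_karyotype_model <- function(tree, tip_states, model = "M0", y_max = 35,
                                method = c("musse", "mkn"), focal = NULL,
                                sampling_f = 1,
                                root = NULL, condition_surv = FALSE,
                                n_starts = 3, lower = -8, upper = 1,
                                seed = NULL, control = list(maxit = 500)) {
  method <- match.arg(method)
  if (!model %in% names(model_params)) stop("unknown model: ", model)
  if (model_grouped[[model]] && is.null(focal))
    stop("models M2/M3 need a 'focal' karyotype set")
  if (model == "M0prime" && length(sampling_f) == 1L && is.null(focal))
    warning("M0prime is meant to reuse the M2 group sampling fractions")
  space <- karyo_states(y_max)
  n <- nrow(space)

  if (is.data.frame(tip_states)) {
    bound <- attach_tip_states(tree, tip_states, space)
    tree <- bound$tree
    tip_states <- bound$tip_states
  }
  ts <- tip_state_indices(tree, tip_states, n)
  names(ts) <- tree$tip.label

  focal_idx <- integer(0)
  if (!is.null(focal)) {
    focal <- as.matrix(focal)
    focal_idx <- state_index(space, focal[, 1], focal[, 2])
    if (any(is.na(focal_idx))) stop("focal karyotypes outside the state space")
  }
  # per-state sampling fractions
  f_states <- rep(1, n)
  if (length(sampling_f) == 2L && all(c("focal", "other") %in% names(sampling_f))) {
    f_states[] <- sampling_f[["other"]]
    f_states[focal_idx] <- sampling_f[["focal"]]
  } else f_states[] <- sampling_f[1]

  pnames <- model_params[[model]]
  if (method == "mkn") {
    if (model_grouped[[model]])
      stop("M2/M3 require the MuSSE likelihood (method = \"musse\")")
    pnames <- setdiff(pnames, c("lambda", "mu"))
    if (is.null(root)) root <- "flat"
  } else if (is.null(root)) root <- "fitzjohn"

  loglik_fn <- function(p10) {
    p <- 10^p10
    names(p) <- pnames
    if (method == "mkn") p <- c(p, lambda = 0, mu = 0)
    rates <- params_to_rates(model, p)
    Q <- karyo_rate_matrix(space, rates)
    if (method == "mkn") {
      mkn_loglik(tree, ts, Q, root = root)
    } else {
      lm <- state_vectors(space, rates, focal_idx)
      musse_loglik(tree, ts, Q, lm$lambda, lm$mu, sampling_f = f_states,
                   root = root, condition_surv = condition_surv)
    }
  }
  neg <- function(p10) {
    ll <- tryCatch(loglik_fn(p10), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # starting points on log10 scale
  npar <- length(pnames)
  yule_lambda <- max((ape::Ntip(tree) - 2) / sum(tree$edge.length), 1e-4)
  heur <- stats::setNames(rep(log10(0.01), npar), pnames)
  heur[grepl("^lambda", pnames)] <- log10(yule_lambda)
  heur[grepl("^mu", pnames)] <- log10(yule_lambda / 2)
  starts <- list(stats::setNames(rep(log10(0.1), npar), pnames), heur)
  n_rand <- max(0L, n_starts - length(starts))
  starts <- c(starts, with_seed(seed, lapply(seq_len(n_rand), function(i)
    stats::setNames(stats::runif(npar, -4, -1), pnames))))
  starts <- starts[seq_len(max(1, n_starts))]

  best <- NULL
  trace <- list()
  for (s in starts) {
    opt <- stats::optim(s, neg, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = control)
    trace[[length(trace) + 1L]] <- list(start = s, value = -opt$value,
                                        convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  est10 <- best$par
  p <- 10^est10
  names(p) <- pnames
  if (method == "mkn") p <- c(p, lambda = 0, mu = 0)
  rates <- params_to_rates(model, p)
  out <- list(model = model, method = method,
              estimates = p[pnames], log10_estimates = est10,
              rates = rates, loglik = -best$value,
              npar = npar, converged = best$convergence == 0,
              root = root, condition_surv = condition_surv,
              space = space, y_max = y_max, focal = focal,
              focal_idx = focal_idx, sampling_f = f_states,
              tree = tree, tip_states = ts, trace = trace)
  class(out) <- "karyo_fit"
  out
}

#' @export
print.karyo_fit <- function(x, ...) {
  cat(sprintf("Karyotype evolution model %s (%s likelihood), %d free parameters\n",
              x$model, x$method, x$npar))
  cat(sprintf("  log-likelihood: %.4f  (converged: %s)\n",
              x$loglik, x$converged))
  est <- x$estimates
  cat("  estimates:\n")
  for (nm in names(est)) cat(sprintf("    %-9s %.4g\n", nm, est[[nm]]))
  if (est[["k1"]] > 0)
    cat(sprintf("    %-9s %.4g\n", "K_f", est[["k2"]] / est[["k1"]]))
  k4 <- if ("k4" %in% names(est)) est[["k4"]] else est[["k3"]]
  if (est[["k3"]] > 0)
    cat(sprintf("    %-9s %.4g\n", "K_i", k4 / est[["k3"]]))
  invisible(x)
}

#' @export
summary.karyo_fit <- function(object, ...) {
  est <- object$estimates
  k4 <- if ("k4" %in% names(est)) est[["k4"]] else est[["k3"]]
  out <- list(model = object$model, method = object$method,
              estimates = est, loglik = object$loglik, npar = object$npar,
              K_f = unname(est[["k2"]] / est[["k1"]]),
              K_i = unname(k4 / est[["k3"]]),
              n_tips = ape::Ntip(object$tree),
              y_max = object$y_max, converged = object$converged,
              root = object$root)
  class(out) <- "summary.karyo_fit"
  out
}

#' @export
print.summary.karyo_fit <- function(x, ...) {
  cat(sprintf("Model %s fit to %d tips (y_max = %d, %s likelihood, %s root)\n",
              x$model, x$n_tips, x$y_max, x$method, x$root))
  cat(sprintf("log-likelihood %.4f with %d free parameters\n", x$loglik, x$npar))
  print(data.frame(estimate = unlist(x$estimates)))
  cat(sprintf("K_f = %.4g, K_i = %.4g\n", x$K_f, x$K_i))
  invisible(x)
}

#' @export
coef.karyo_fit <- function(object, log10 = FALSE, ...) {
  if (log10) object$log10_estimates else object$estimates
}

#' @export
logLik.karyo_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' Simulate tip karyotypes under a fitted model
#'
#' Forward-simulates the fitted transition process down the fitted tree
#' (or a supplied one), starting from a root state.
#'
#' @param object A `karyo_fit`.
#' @param nsim Number of replicate simulations.
#' @param seed Optional seed.
#' @param tree Tree to simulate on (default: the fitted tree).
#' @param root_state Root karyotype `c(x, y)` or state index (default:
#'   mode of the fitted stationary distribution).
#' @param ... Unused.
#' @return A list of `nsim` tip-state vectors (see
#'   [sim_karyotype_tips()]).
#' @export
simulate.karyo_fit <- function(object, nsim = 1, seed = NULL,
                               tree = object$tree, root_state = NULL, ...) {
  Q <- karyo_rate_matrix(object$space, object$rates)
  if (is.null(root_state)) {
    est <- object$estimates
    k4 <- if ("k4" %in% names(est)) est[["k4"]] else est[["k3"]]
    sd <- suppressWarnings(
      stationary_karyotype(est[["k2"]] / est[["k1"]], k4 / est[["k3"]],
                           y_max = object$y_max))
    i <- which.max(sd$prob)
    root_state <- c(sd$x[i], sd$y[i])
  }
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sim_karyotype_tips(tree, Q, root_state)))
}

#' Likelihood-ratio test between nested karyotype models
#'
#' @param full,null `karyo_fit` objects; `null` must be nested in
#'   `full` (registered nestings: M1 in M0/M3, M3 in M2, M0prime in M2,
#'   M0 in M4).
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "karyo_fit"), inherits(null, "karyo_fit"))
  same <- full$model == null$model
  nested <- same || any(model_nestings[, 1] == null$model &
                          model_nestings[, 2] == full$model)
  if (!nested)
    stop(sprintf("model %s is not nested in %s", null$model, full$model))
  stat <- max(0, 2 * (full$loglik - null$loglik))
  df <- full$npar - null$npar
  p <- if (df == 0) as.numeric(stat <= 1e-8) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

#' @export
anova.karyo_fit <- function(object, ...) {
  others <- list(...)
  if (!length(others)) stop("supply a second fit to compare against")
  null <- others[[1]]
  if (null$npar > object$npar) { tmp <- object; object <- null; null <- tmp }
  res <- likelihood_ratio_test(object, null)
  out <- data.frame(model = c(null$model, object$model),
                    npar = c(null$npar, object$npar),
                    logLik = c(null$loglik, object$loglik),
                    statistic = c(NA, res$statistic),
                    df = c(NA, res$df),
                    p.value = c(NA, res$p.value))
  class(out) <- c("anova", "data.frame")
  out
}
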
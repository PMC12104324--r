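#' Fit the bilateral progression model to a cohort
#'
#' Samples the posterior of the spread parameters given a cohort of observed
#' involvement patterns, under a uniform prior over the unit cube, using the
#' differential-evolution ensemble sampler. Walkers start uniformly in the
#' cube; the burn-in runs until the mean integrated autocorrelation time has
#' stabilized (relative change below `rel_tol`) and is exceeded
#' `trust_factor`-fold by the chain length; after convergence a further
#' `n_keep * thin` steps are run and every `thin`-th ensemble state is
#' retained, giving `n_keep` draws per walker.
#'
#' @param cohort a cohort data.frame ([read_cohort()] / [simulate_cohort()]).
#' @param graph a [lymph_graph()].
#' @param walkers_per_dim walkers per free parameter (>= 2 effective).
#' @param max_steps hard cap on burn-in length.
#' @param check_every autocorrelation re-estimation interval (ensemble steps).
#' @param rel_tol,trust_factor convergence thresholds, see
#'   [check_convergence()].
#' @param n_keep retained draws per walker after convergence.
#' @param thin spacing (ensemble steps) between retained draws.
#' @param p_early,t_max fixed model constants.
#' @param seed integer seed; fixing it makes the fit bit-reproducible.
#' @param init walker initialization: `"map_ball"` (default) runs a short
#'   bounded quasi-Newton search for the posterior mode from the best of a
#'   set of random draws and scatters the walkers in a small ball around it,
#'   so a capped-length burn-in starts inside the typical set; `"cube"`
#'   draws every walker uniformly from the unit cube (the prior).
#' @param on_nonconvergence `"error"` or `"warn"` when `max_steps` is
#'   reached without meeting the convergence criteria.
#' @param verbose print progress.
#' @return An object of class `lymph_fit` with elements `draws` (matrix,
#'   one row per retained draw, columns named per [theta_names()]),
#'   `accept_frac`, `tau_history`, `converged`, `burn_in`, `seed`, `graph`
#'   and the fixed constants.
#' @export
lymph_fit <- function(cohort, graph = lymph_graph(),
                      walkers_per_dim = 12L, max_steps = 5000L,
                      check_every = 100L, rel_tol = 5.0e-2,
                      trust_factor = 50, n_keep = 10L, thin = 10L,
                      p_early = 0.3, t_max = 10L, seed = NULL,
                      init = c("map_ball", "cube"),
                      on_nonconvergence = c("error", "warn"),
                      verbose = FALSE) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nms <- theta_names(graph)
  n_dim <- length(nms)
  n_walkers <- max(as.integer(walkers_per_dim) * n_dim, 2L * n_dim)
  groups <- compile_cohort(cohort, graph)
  lp_fun <- make_log_posterior(groups, graph, p_early = p_early, t_max = t_max)

  pos <- if (init == "map_ball") {
    map_ball_init(lp_fun, n_walkers, n_dim)
  } else {
    matrix(stats::runif(n_walkers * n_dim), n_walkers, n_dim)
  }
  chain <- array(NA_real_, c(0L, n_walkers, n_dim))
  tau_history <- numeric(0)
  converged <- FALSE
  steps_done <- 0L
  state <- list(pos = pos)
  while (steps_done < max_steps) {
    batch <- min(check_every, max_steps - steps_done)
    run <- ensemble_mcmc(lp_fun, state$pos, batch)
    state <- run
    chain <- abind_steps(chain, run$chain)
    steps_done <- steps_done + batch
    # estimate the autocorrelation time on the most recent half of the
    # chain, so the initial transient does not inflate it indefinitely
    recent <- chain[(nrow(chain) %/% 2L + 1L):nrow(chain), , , drop = FALSE]
    tau_history <- c(tau_history, mean(autocorr_time(recent)))
    conv <- check_convergence(tau_history, steps_done,
                              rel_tol = rel_tol, trust_factor = trust_factor)
    if (verbose) {
      message(sprintf("step %d: tau = %.1f (trust limit %.1f), accept = %.2f",
                      steps_done, conv$tau, conv$trust_limit, run$accept_frac))
    }
    if (isTRUE(conv$converged)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- sprintf(
      "sampler did not converge in %d steps (tau = %.1f, trust limit %.1f, last relative change %.3f)",
      steps_done, utils::tail(tau_history, 1L),
      steps_done / trust_factor,
      utils::tail(abs(diff(tau_history)) / utils::tail(tau_history, -1L), 1L))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  post <- ensemble_mcmc(lp_fun, state$pos, as.integer(n_keep) * as.integer(thin))
  keep_idx <- seq(as.integer(thin), as.integer(n_keep) * as.integer(thin),
                  by = as.integer(thin))
  draws <- do.call(rbind, lapply(keep_idx, function(s) post$chain[s, , ]))
  colnames(draws) <- nms

  structure(
    list(
      draws = draws,
      accept_frac = post$accept_frac,
      tau_history = tau_history,
      converged = converged,
      burn_in = steps_done,
      n_walkers = n_walkers,
      graph = graph,
      p_early = p_early,
      t_max = t_max,
      seed = seed,
      n_patients = sum(vapply(unclass(groups), function(g) sum(g$n), integer(1))),
      log_prob = max(post$lp)
    ),
    class = "lymph_fit"
  )
}

# mode search from the best of a handful of random draws, then a tight
# Gaussian ball around the optimum, clipped to the open cube
map_ball_init <- function(lp_fun, n_walkers, n_dim, n_starts = 64L,
                          ball_sd = 0.005) {
  starts <- matrix(stats::runif(n_starts * n_dim), n_starts, n_dim)
  lps <- apply(starts, 1L, lp_fun)
  x0 <- starts[which.max(lps), ]
  opt <- stats::optim(
    x0, function(x) -lp_fun(x), method = "L-BFGS-B",
    lower = rep(1e-6, n_dim), upper = rep(1 - 1e-6, n_dim),
    control = list(maxit = 500L)
  )
  center <- opt$par
  pos <- matrix(stats::rnorm(n_walkers * n_dim, mean = rep(center, each = n_walkers),
                             sd = ball_sd), n_walkers, n_dim)
  pmin(pmax(pos, 1e-6), 1 - 1e-6)
}

abind_steps <- function(a, b) {
  if (dim(a)[1L] == 0L) return(b)
  out <- array(NA_real_, c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

#' @export
print.lymph_fit <- function(x, ...) {
  cat("Bilateral lymphatic progression model fit\n")
  cat(sprintf("  %d patients, %d free parameters, %d walkers\n",
              x$n_patients, ncol(x$draws), x$n_walkers))
  cat(sprintf("  burn-in %d steps (%s), %d retained draws, acceptance %.2f\n",
              x$burn_in, if (x$converged) "converged" else "NOT converged",
              nrow(x$draws), x$accept_frac))
  invisible(x)
}

#' @export
summary.lymph_fit <- function(object, ...) {
  m <- colMeans(object$draws)
  s <- apply(object$draws, 2L, stats::sd)
  out <- data.frame(mean = m, sd = s)
  class(out) <- c("summary.lymph_fit", "data.frame")
  out
}

#' @export
print.summary.lymph_fit <- function(x, digits = 4, ...) {
  cat("Posterior parameter estimates (mean and standard deviation):\n")
  print.data.frame(round(x, digits))
  invisible(x)
}

#' @export
coef.lymph_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Posterior-mean parameters of a fit
#'
#' @param fit a `lymph_fit` object.
#' @return A [lymph_params()] object at the posterior means.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "lymph_fit"))
  theta_to_params(coef(fit), fit$graph, p_early = fit$p_early,
                  t_max = fit$t_max)
}

#' @export
logLik.lymph_fit <- function(object, ...) {
  structure(object$log_prob, df = ncol(object$draws), class = "logLik")
}

#' Predict occult-disease risk from a fitted model
#'
#' Evaluates the marginal involvement risk of a queried level for a clinical
#' scenario, once per retained posterior draw, and returns the risk
#' histogram together with its mean.
#'
#' @param object a `lymph_fit`.
#' @param scenario a [risk_scenario()].
#' @param side,level the queried neck side and level.
#' @param ... unused.
#' @return A list with `mean` and per-draw `risks`.
#' @export
predict.lymph_fit <- function(object, scenario, side = "contra",
                              level = "II", ...) {
  marginal_risk(scenario, object$draws, side = side, level = level,
                graph = object$graph)
}

#' Simulate cohorts from a fitted model
#'
#' Draws a synthetic cohort at the posterior-mean parameters (posterior
#' predictive simulation at the point estimate).
#'
#' @param object a `lymph_fit`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_early,n_advanced cohort composition.
#' @param ... passed to [simulate_cohort()].
#' @return A `lymph_cohort`, or a list of them if `nsim > 1`.
#' @export
simulate.lymph_fit <- function(object, nsim = 1, seed = NULL,
                               n_early = 100L, n_advanced = 100L, ...) {
  params <- fitted_params(object)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(seq_len(nsim), function(i) {
    simulate_cohort(params, n_early = n_early, n_advanced = n_advanced, ...)
  })
  if (nsim == 1) out[[1L]] else out
}

#' Diagnostic plots for a fit
#'
#' Left: the successive autocorrelation-time estimates over the burn-in
#' against the trust limit. Right: posterior histogram of a chosen
#' parameter.
#'
#' @param x a `lymph_fit`.
#' @param parameter parameter name to histogram.
#' @param ... unused.
#' @export
plot.lymph_fit <- function(x, parameter = colnames(x$draws)[1L], ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  steps <- seq_along(x$tau_history) * (x$burn_in / length(x$tau_history))
  graphics::plot(steps, x$tau_history, type = "b", xlab = "ensemble step",
                 ylab = "mean autocorrelation time",
                 main = "burn-in monitoring")
  graphics::lines(steps, steps / 50, lty = 2)
  graphics::hist(x$draws[, parameter], breaks = 30, main = parameter,
                 xlab = "value")
  invisible(x)
}
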
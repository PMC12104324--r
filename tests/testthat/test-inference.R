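test_that("log-posterior support is the unit cube with a uniform prior", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  co <- simulate_cohort(p, 50, 50, seed = 23)
  groups <- bilymph:::compile_cohort(co, g2)
  th <- as_theta(p)

  bad <- th; bad[3] <- 1.5
  expect_identical(log_posterior(bad, groups, g2), -Inf)
  bad2 <- th; bad2[1] <- NaN
  expect_identical(log_posterior(bad2, groups, g2), -Inf)

  # inside the cube the posterior is the likelihood (uniform prior)
  expect_equal(log_posterior(th, groups, g2), cohort_log_likelihood(co, p))
  th2 <- pmin(pmax(th + 0.05, 0.01), 0.99)
  p2 <- theta_to_params(th2, g2)
  expect_equal(log_posterior(th, groups, g2) - log_posterior(th2, groups, g2),
               cohort_log_likelihood(co, p) - cohort_log_likelihood(co, p2))
})

test_that("the sampler's fast posterior closure matches the reference path", {
  g <- lymph_graph()
  p <- ref_params()
  co <- simulate_cohort(p, 150, 150, seed = 67, missing_rate = 0.1)
  # some records with unknown midline status exercise that branch too
  co$midline_extension[1:10] <- NA
  groups <- bilymph:::compile_cohort(co, g)
  fast <- bilymph:::make_log_posterior(groups, g)
  set.seed(69)
  for (rep in 1:5) {
    th <- runif(19)
    expect_equal(fast(th), log_posterior(th, groups, g), tolerance = 1e-12)
  }
  expect_identical(fast(replace(runif(19), 4, 2)), -Inf)
})

test_that("convergence rule combines stability and the trust threshold", {
  # stable estimate well below the trust limit
  expect_true(check_convergence(c(100, 99.9), 10000)$converged)
  # estimate above chain_length / 50
  expect_false(check_convergence(c(300, 300), 10000)$converged)
  # estimate still drifting
  expect_false(check_convergence(c(100, 125), 10000)$converged)
  # a single estimate is never trusted
  expect_false(check_convergence(150, 10000)$converged)
})

test_that("autocorrelation time is near one for white noise", {
  set.seed(29)
  chain <- array(rnorm(2000 * 4 * 2), c(2000, 4, 2))
  tau <- autocorr_time(chain)
  expect_length(tau, 2)
  expect_true(all(tau > 0.5 & tau < 2))
  # strongly correlated AR(1) series has a much larger time
  ar <- array(0, c(2000, 4, 1))
  for (w in 1:4) ar[, w, 1] <- as.vector(arima.sim(list(ar = 0.95), 2000))
  expect_gt(autocorr_time(ar)[1], 10)
})

test_that("ensemble sampler recovers a known two-parameter posterior", {
  # single level per side: free tumor-spread rates on both sides, everything
  # else held at truth; compare the sampled posterior with a grid evaluation
  g1 <- toy_graph_1()
  truth <- lymph_params(g1, ipsi_spread = c(II = 0.35),
                        contra_spread = c(II = 0.1), mixing = 0.4,
                        arc_spread = numeric(0), p_adv = 0.45,
                        midline_prob = 0.1)
  co <- simulate_cohort(truth, 400, 400, seed = 31)
  groups <- bilymph:::compile_cohort(co, g1)
  fixed <- as_theta(truth)
  lp2 <- function(xy) {
    th <- fixed
    th[c("ipsi_II", "contra_II")] <- xy
    log_posterior(th, groups, g1)
  }
  grid <- seq(0.005, 0.995, by = 0.005)
  ll_i <- vapply(grid, function(x) lp2(c(x, 0.1)), numeric(1))
  ll_c <- vapply(grid, function(x) lp2(c(0.35, x)), numeric(1))

  set.seed(33)
  run <- ensemble_mcmc(lp2, matrix(runif(24 * 2, 0.05, 0.6), 24, 2),
                       n_steps = 400)
  draws <- run$chain[201:400, , ]
  m_i <- mean(draws[, , 1]); s_i <- sd(draws[, , 1])
  m_c <- mean(draws[, , 2]); s_c <- sd(draws[, , 2])
  # posterior means sit near the conditional grid maxima
  expect_lt(abs(m_i - grid[which.max(ll_i)]), 3 * s_i)
  expect_lt(abs(m_c - grid[which.max(ll_c)]), 3 * s_c)
  # and the grid maxima are near the generating truth
  expect_lt(abs(grid[which.max(ll_i)] - 0.35), 0.05)
  expect_lt(abs(grid[which.max(ll_c)] - 0.1), 0.05)
})

test_that("sampler runs are seed-reproducible and stay in the cube", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  co <- simulate_cohort(p, 120, 120, seed = 37)
  fit_once <- function() {
    lymph_fit(co, g2, walkers_per_dim = 3, max_steps = 400,
              check_every = 100, n_keep = 5, thin = 5, seed = 41,
              on_nonconvergence = "warn")
  }
  f1 <- suppressWarnings(fit_once())
  f2 <- suppressWarnings(fit_once())
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws >= 0 & f1$draws <= 1))
  expect_equal(nrow(f1$draws), 5 * f1$n_walkers)
  expect_equal(colnames(f1$draws), theta_names(g2))
  # summaries are recomputable from the stored draws
  s <- summary(f1)
  expect_equal(s$mean, unname(colMeans(f1$draws)))
  expect_equal(s$sd, unname(apply(f1$draws, 2, sd)))
  expect_equal(coef(f1), colMeans(f1$draws))
})

test_that("non-convergence within the step cap fails loudly", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  co <- simulate_cohort(p, 60, 60, seed = 43)
  expect_error(
    lymph_fit(co, g2, walkers_per_dim = 3, max_steps = 60, check_every = 30,
              seed = 47),
    "did not converge")
})

test_that("draws persist to CSV and read back with metadata", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  co <- simulate_cohort(p, 100, 100, seed = 53)
  fit <- suppressWarnings(
    lymph_fit(co, g2, walkers_per_dim = 3, max_steps = 200, check_every = 100,
              n_keep = 3, thin = 2, seed = 59, on_nonconvergence = "warn"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  meta <- attr(back, "meta")
  attr(back, "meta") <- NULL
  expect_equal(unname(back), unname(fit$draws), tolerance = 1e-12)
  expect_equal(colnames(back), colnames(fit$draws))
  expect_equal(meta$seed, "59")
})
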
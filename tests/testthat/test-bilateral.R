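test_that("midline mixing interpolates between the two spread maps", {
  g <- lymph_graph()
  base <- ref_params(g)
  p0 <- theta_to_params(replace(as_theta(base), "mixing", 0), g)
  expect_equal(mixed_contra_spread(p0), p0$contra_spread)
  p1 <- theta_to_params(replace(as_theta(base), "mixing", 1), g)
  expect_equal(unname(mixed_contra_spread(p1)), unname(p1$ipsi_spread))
  # arithmetic on the reference estimates for level II
  expect_equal(mixed_contra_spread(base)[["II"]],
               0.3387 * 0.3489 + (1 - 0.3387) * 0.0246,
               tolerance = 1e-12)
})

test_that("midline evolution satisfies its conservation laws", {
  set.seed(21)
  for (rep in 1:4) {
    p <- random_params(lymph_graph())
    ev <- midline_evolution(p)
    t <- 0:p$t_max
    # the lateralized branch starts with certainty and decays geometrically
    expect_equal(ev$lam_false[1, 1], 1)
    expect_equal(unname(rowSums(ev$lam_false)),
                 (1 - p$midline_prob)^t, tolerance = 1e-12)
    # no tumor has crossed before the first step
    expect_equal(ev$lam_true[1, ], rep(0, 64))
    # both branches together conserve probability
    expect_equal(rowSums(ev$lam_false) + rowSums(ev$lam_true),
                 rep(1, p$t_max + 1), tolerance = 1e-12)
    # closed form of the crossing probability
    expect_equal(unname(rowSums(ev$lam_true)),
                 1 - (1 - p$midline_prob)^t, tolerance = 1e-12)
  }
})

test_that("joint distribution normalizes and degenerates correctly", {
  set.seed(31)
  g <- lymph_graph()
  for (rep in 1:4) {
    p <- random_params(g)
    for (tg in c("early", "advanced")) {
      tot <- sum(joint_state_dist(p, tg, FALSE)) +
        sum(joint_state_dist(p, tg, TRUE))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
  # with no crossing probability the crossed slice is empty
  p0 <- theta_to_params(replace(as_theta(ref_params()), "midline_prob", 0), g)
  expect_equal(sum(joint_state_dist(p0, "early", TRUE)), 0)
})

test_that("joint distribution equals the exhaustive trajectory oracle", {
  set.seed(41)
  g2 <- toy_graph_2()
  for (rep in 1:2) {
    th <- runif(2 * 2 + 1 + 3)
    p <- theta_to_params(th, g2, t_max = 3L)
    for (tg in c("early", "advanced")) {
      oracle <- oracle_joint(p, tg)
      expect_equal(joint_state_dist(p, tg, FALSE), oracle$lateralized,
                   tolerance = 1e-10)
      expect_equal(joint_state_dist(p, tg, TRUE), oracle$crossed,
                   tolerance = 1e-10)
    }
  }
})

test_that("identical spread maps make the two crossing branches proportional", {
  g <- lymph_graph()
  th <- as_theta(ref_params())
  # mixing 0 with contra == ipsi rates: crossing changes nothing but the flag
  th[paste0("contra_", g$lnl_names)] <- th[paste0("ipsi_", g$lnl_names)]
  th["mixing"] <- 0
  p <- theta_to_params(th, g)
  ev <- midline_evolution(p)
  for (t in 1:p$t_max) {
    cond_false <- ev$lam_false[t + 1, ] / sum(ev$lam_false[t + 1, ])
    cond_true <- ev$lam_true[t + 1, ] / sum(ev$lam_true[t + 1, ])
    expect_equal(cond_false, cond_true, tolerance = 1e-10)
  }
})

test_that("ipsilateral and contralateral involvement are positively coupled", {
  # the two sides share no arcs, but both progress with elapsed time
  p <- ref_params()
  S <- lnl_states(6)
  ind <- as.numeric(rowSums(S) > 0)  # any involvement on a side
  for (tg in c("early", "advanced")) {
    M <- joint_state_dist(p, tg, FALSE) + joint_state_dist(p, tg, TRUE)
    p_i <- sum(ind * rowSums(M))
    p_c <- sum(colSums(M) * ind)
    p_both <- as.numeric(ind %*% M %*% ind)
    expect_gt(p_both, p_i * p_c)
  }
})

test_that("patient likelihood marginalizes missing information", {
  p <- toy_params_2(t_max = 10L)
  all_missing <- patient_log_likelihood(p, "early", NA, c(NA, NA), c(NA, NA))
  expect_equal(all_missing, 0)

  # known pattern with known flag picks one entry of the joint
  M <- joint_state_dist(p, "advanced", TRUE)
  ll <- patient_log_likelihood(p, "advanced", TRUE, c(1, 0), c(0, 0))
  expect_equal(ll, log(M[3, 1]))

  # unknown flag sums both branches
  Mf <- joint_state_dist(p, "advanced", FALSE)
  ll_na <- patient_log_likelihood(p, "advanced", NA, c(1, 0), c(0, 0))
  expect_equal(ll_na, log(M[3, 1] + Mf[3, 1]))

  expect_error(patient_log_likelihood(p, NA, TRUE, c(1, 0), c(0, 0)),
               "T-group")
})

test_that("cohort likelihood is additive and permutation invariant", {
  p <- ref_params()
  co <- simulate_cohort(p, 20, 20, seed = 5)
  ll <- cohort_log_likelihood(co, p)
  expect_lt(ll, 0)

  one <- co[7, , drop = FALSE]
  ll_one <- cohort_log_likelihood(one, p)
  dup <- rbind(one, one)
  dup$id <- c("a", "b")
  expect_equal(cohort_log_likelihood(dup, p), 2 * ll_one)

  set.seed(99)
  shuffled <- co[sample(nrow(co)), ]
  expect_equal(cohort_log_likelihood(shuffled, p), ll)

  # matches the sum of patient-level evaluations
  g <- lymph_graph()
  lnl <- g$lnl_names
  by_hand <- sum(vapply(seq_len(nrow(co)), function(i) {
    patient_log_likelihood(
      p, co$t_group[i], co$midline_extension[i],
      as.numeric(co[i, paste0("consensus_ipsi_", lnl)]),
      as.numeric(co[i, paste0("consensus_contra_", lnl)]))
  }, numeric(1)))
  expect_equal(ll, by_hand, tolerance = 1e-8)
})
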
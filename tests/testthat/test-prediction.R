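test_that("diagnosis posterior normalizes and matches the double-loop oracle", {
  set.seed(51)
  g2 <- toy_graph_2()
  for (rep in 1:3) {
    p <- theta_to_params(runif(8), g2)
    sc <- risk_scenario(sample(c("early", "advanced"), 1),
                        sample(c(TRUE, FALSE), 1),
                        ipsi_involved = sample(c("II", "III"), 1),
                        graph = g2)
    post <- posterior_involvement(sc, p)
    expect_equal(sum(post), 1, tolerance = 1e-10)
    expect_true(all(post >= 0))
    expect_equal(post, oracle_posterior(sc, p), tolerance = 1e-10)
  }
})

test_that("a perfect modality makes the posterior a point mass", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  sc <- risk_scenario("early", FALSE, ipsi_involved = "II", graph = g2)
  # overwrite both sides with a perfect modality
  sc$ipsi$sensitivity <- sc$ipsi$specificity <- rep(1, 2)
  sc$contra$sensitivity <- sc$contra$specificity <- rep(1, 2)
  post <- posterior_involvement(sc, p)
  expect_equal(post[3, 1], 1)  # ipsi (1,0), contra (0,0)
  expect_equal(sum(post != 0), 1L)
})

test_that("an uninformative diagnosis returns the renormalized prior slice", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  sc <- risk_scenario("advanced", TRUE, assume_negative = FALSE, graph = g2)
  post <- posterior_involvement(sc, p)
  M <- joint_state_dist(p, "advanced", TRUE)
  expect_equal(post, M / sum(M), tolerance = 1e-12)
})

test_that("perfect-modality risk equals the conditional prior of involvement", {
  g2 <- toy_graph_2()
  p <- toy_params_2(t_max = 10L)
  sc <- risk_scenario("early", FALSE, ipsi_involved = "II", graph = g2)
  sc$ipsi$sensitivity <- sc$ipsi$specificity <- rep(1, 2)
  sc$contra$sensitivity <- sc$contra$specificity <- rep(1, 2)
  r <- marginal_risk(sc, p, "ipsi", "III")
  M <- joint_state_dist(p, "early", FALSE)
  # condition the prior on ipsi II involved & III healthy, contra healthy
  expect_equal(r, 0)  # III diagnosed healthy by a perfect modality: no occult risk
  # with the queried level left unexamined, risk is the conditional prior
  sc2 <- risk_scenario("early", FALSE, ipsi_involved = "II",
                       assume_negative = FALSE, graph = g2)
  sc2$ipsi$sensitivity <- sc2$ipsi$specificity <- rep(1, 2)
  sc2$contra$sensitivity <- sc2$contra$specificity <- rep(1, 2)
  r2 <- marginal_risk(sc2, p, "ipsi", "III")
  cond <- sum(M[4, ]) / sum(M[c(3, 4), ])  # P(III | II) among ipsi states
  expect_equal(r2, cond, tolerance = 1e-12)
})

test_that("risk over a draw matrix returns the per-draw histogram", {
  g2 <- toy_graph_2()
  set.seed(61)
  draws <- matrix(runif(5 * 8), 5, 8)
  sc <- risk_scenario("early", FALSE, ipsi_involved = "II", graph = g2)
  out <- marginal_risk(sc, draws, "contra", "II", graph = g2)
  expect_length(out$risks, 5)
  expect_equal(out$mean, mean(out$risks))
  expect_true(all(out$risks >= 0 & out$risks <= 1))
})

test_that("querying a level diagnosed involved is flagged", {
  p <- ref_params()
  sc <- risk_scenario("early", FALSE, ipsi_involved = "II")
  expect_message(marginal_risk(sc, p, "ipsi", "II"), "not an occult")
})

test_that("FNA confirmation of an upstream level raises downstream risk", {
  # eliminating false positives upstream must not lower downstream risk
  p <- ref_params()
  base <- risk_scenario("advanced", TRUE, ipsi_involved = c("II", "III", "IV"),
                        contra_involved = "II")
  fna <- risk_scenario("advanced", TRUE, ipsi_involved = c("II", "III", "IV"),
                       contra_involved = "II", fna_contra = "II")
  expect_gt(marginal_risk(fna, p, "contra", "III"),
            marginal_risk(base, p, "contra", "III"))
  # same check one level further down
  base4 <- risk_scenario("advanced", TRUE,
                         ipsi_involved = c("II", "III", "IV"),
                         contra_involved = c("II", "III"))
  fna4 <- risk_scenario("advanced", TRUE,
                        ipsi_involved = c("II", "III", "IV"),
                        contra_involved = c("II", "III"), fna_contra = "III")
  expect_gt(marginal_risk(fna4, p, "contra", "IV"),
            marginal_risk(base4, p, "contra", "IV"))
})

test_that("predicted prevalence marginalizes masked levels", {
  p <- ref_params()
  # fully masked pattern has prevalence one
  expect_equal(predicted_prevalence(p, "early", FALSE), 1, tolerance = 1e-12)
  # prevalence of a level is between zero and one, larger for advanced
  early <- predicted_prevalence(p, "early", FALSE, contra = c(II = 1))
  adv <- predicted_prevalence(p, "advanced", FALSE, contra = c(II = 1))
  expect_gt(adv, early)
  # complementary patterns add to one
  healthy <- predicted_prevalence(p, "early", FALSE, contra = c(II = 0))
  expect_equal(early + healthy, 1, tolerance = 1e-12)
  # requesting an impossible slice errors
  p0 <- theta_to_params(replace(as_theta(p), "midline_prob", 0), p$graph)
  expect_error(predicted_prevalence(p0, "early", TRUE, contra = c(II = 1)),
               "zero probability")
})

test_that("observed-prevalence posterior is the stated beta distribution", {
  post <- prevalence_posterior(27, 379)
  expect_equal(post$shape1, 28)
  expect_equal(post$shape2, 353)
  expect_equal(post$mode, 27 / 379)
  expect_equal(post$mean, 28 / 381)
  # no data: uniform prior
  flat <- prevalence_posterior(0, 0)
  expect_equal(flat$density(c(0.1, 0.5, 0.9)), rep(1, 3))
  expect_error(prevalence_posterior(5, 3), "k <= n")
})
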
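test_that("observation likelihood matches hand-computed cases", {
  expect_equal(observation_likelihood(c(1, 0, 0), 1), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(observation_likelihood(c(1, 0, 0), 0), c(0, 1/2, 1/2), tolerance = 1e-12)
  expect_equal(observation_likelihood(c(1, 1, 0), 1), c(1/2, 1/2, 0), tolerance = 1e-12)
  expect_error(observation_likelihood(c(0, 0, 0), 1), class = "wcst_impossible_observation")
})

test_that("posterior update follows Bayes rule and reports the marginal", {
  u <- rep(1/3, 3)
  up <- posterior_update(u, c(1, 0, 0))
  expect_equal(up$posterior, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(up$marginal, 1/3, tolerance = 1e-12)
  up <- posterior_update(u, c(0, 1/2, 1/2))
  expect_equal(up$posterior, c(0, 1/2, 1/2), tolerance = 1e-12)
  expect_equal(up$marginal, 1/3, tolerance = 1e-12)
  # uniform likelihood leaves any prior unchanged
  pr <- c(0.2, 0.5, 0.3)
  expect_equal(posterior_update(pr, c(1, 1, 1))$posterior, pr, tolerance = 1e-12)
  expect_error(posterior_update(c(1, 0, 0), c(0, 1, 1)), class = "wcst_zero_probability")
})

test_that("matching signal gating follows the feedback by default", {
  expect_equal(matching_signal(c(1, 0, 0), 1), c(1L, 0L, 0L))
  expect_equal(matching_signal(c(1, 0, 0), 0), c(0L, 0L, 0L))
  expect_equal(matching_signal(c(1, 1, 0), 1), c(1L, 1L, 0L))
  expect_equal(matching_signal(c(1, 0, 0), 0, gating = "always"), c(1L, 0L, 0L))
})

test_that("compact activation update reproduces hand-evaluated cases", {
  fl <- 1e-6
  p <- function(l, d) agent_params(l, d, semantics = "compact")
  # positive feedback, delta = 0: matched feature saturates, others floored
  expect_equal(activation_update(c(.5, .5, .5), c(1, 0, 0), 1, p(0.5, 0)),
               c(1 - 1e-15, fl, fl), tolerance = 1e-12)
  # positive feedback, delta = 1: matched feature keeps its activation
  expect_equal(activation_update(c(.5, .5, .5), c(1, 0, 0), 1, p(0.5, 1)),
               c(.5, fl, fl), tolerance = 1e-12)
  # negative feedback, lambda = 0.5, delta = 0: uniform shrink by lambda
  expect_equal(activation_update(c(.5, .5, .5), c(0, 0, 0), 0, p(0.5, 0)),
               c(.25, .25, .25), tolerance = 1e-12)
})

test_that("evidence activation update confirms, damps and retains as documented", {
  p <- agent_params(0.3, 0.4)
  w <- c(0.6, 0.5, 0.4)
  # positive feedback on a color-only match: color engages, others damped
  expect_equal(activation_update(w, c(1, 0, 0), 1, p),
               c(0.6^0.4, 0.3 * 0.5^0.4, 0.3 * 0.4^0.4), tolerance = 1e-12)
  # negative feedback on a color-only match: color damped, others untouched
  expect_equal(activation_update(w, c(1, 0, 0), 0, p),
               c(0.3 * 0.6^0.4, 0.5, 0.4), tolerance = 1e-12)
  # ambiguous positive match engages both matched features
  expect_equal(activation_update(w, c(1, 1, 0), 1, p),
               c(0.6^0.4, 0.5^0.4, 0.3 * 0.4^0.4), tolerance = 1e-12)
})

test_that("stability matrix is row-stochastic with the activations on its diagonal", {
  G <- stability_matrix(c(.5, .5, .5))
  expect_equal(G, matrix(c(.5, .25, .25, .25, .5, .25, .25, .25, .5),
                         3, byrow = TRUE), tolerance = 1e-12)
  G <- stability_matrix(c(1, 0, 0))
  expect_equal(G, matrix(c(1, 0, 0, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE),
               tolerance = 1e-12)
  for (i in 1:20) {
    w <- runif(3)
    G <- stability_matrix(w)
    expect_equal(rowSums(G), c(1, 1, 1))  # exact by construction
    expect_equal(diag(G), w)
  }
})

test_that("predictive update applies the Chapman-Kolmogorov equation", {
  expect_equal(
    predictive_update(c(0, .5, .5), stability_matrix(c(.5, .5, .5))),
    c(.25, .375, .375), tolerance = 1e-12)
  # identity transition leaves the posterior unchanged
  expect_equal(predictive_update(c(.1, .6, .3), stability_matrix(c(1, 1, 1))),
               c(.1, .6, .3), tolerance = 1e-12)
  # the fast algebraic form agrees with the matrix product
  for (i in 1:20) {
    post <- runif(3); post <- post / sum(post)
    w <- runif(3)
    expect_equal(wcstbayes:::.predictive_fast(post, w),
                 predictive_update(post, stability_matrix(w)), tolerance = 1e-14)
  }
})

test_that("belief vectors stay on the simplex and activations in (0, 1]", {
  for (th in list(c(.1, .9), c(.9, .1), c(.5, .5))) {
    s <- run_agent(agent_params(th[1], th[2]), task_config(), seed = 7)
    for (cols in list(c("prior_1", "prior_2", "prior_3"),
                      c("posterior_1", "posterior_2", "posterior_3"))) {
      sums <- rowSums(as.matrix(s[cols]))
      expect_true(all(abs(sums - 1) < 1e-12))
      expect_true(all(as.matrix(s[cols]) >= 0))
    }
    om <- as.matrix(s[c("omega_1", "omega_2", "omega_3")])
    expect_true(all(om >= 1e-6 & om <= 1))
  }
})

test_that("sampled actions never pick cards matching no feature when lapse = 0", {
  s <- run_agent(agent_params(0.2, 0.8), task_config(), seed = 13)
  mv <- cbind(s$match_color, s$match_shape, s$match_number)
  expect_true(all(rowSums(mv) >= 1))
  # and the sampled feature always matches
  expect_true(all(mv[cbind(seq_len(nrow(s)), s$sampled_feature)] == 1))
})

test_that("closed-form action distribution matches empirical sampling frequencies", {
  pred <- c(1/3, 1/3, 1/3)
  tgt <- c(1, 2, 3)  # three distinct matching cards
  q <- action_distribution(pred, tgt, lapse = 0)
  expect_equal(q, c(1/3, 1/3, 1/3, 0), tolerance = 1e-12)
  n <- 1e5
  withr::with_seed(99, {
    acts <- vapply(seq_len(n), function(i) sample_action(pred, tgt, 0)$action,
                   integer(1))
  })
  emp <- tabulate(acts, 4) / n
  band <- 3 * sqrt(pmax(q * (1 - q), 1e-12) / n)
  expect_true(all(abs(emp - q) <= band + 1e-12))
  # degenerate predictive always picks the matching card
  expect_equal(action_distribution(c(1, 0, 0), tgt, 0), c(1, 0, 0, 0))
})

test_that("near-ideal agents err only immediately after rule changes", {
  s <- run_agent(agent_params(1, 0.005), task_config(), seed = 23)
  tfc <- trials_to_first_category(s)$trials
  err <- which(s$feedback == 0 & s$trial > tfc)
  changes <- which(s$rule_change)
  # every late error lies within a short window after some rule change
  for (e in err) {
    expect_true(any(changes < e & e - changes <= 4))
  }
})
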
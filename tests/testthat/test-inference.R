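test_that("single-trial log-likelihood contributions are analytic", {
  # first trial, uniform prior, three distinct matching cards: any matching
  # action contributes log(1/3)
  s1 <- toy_session(1)
  expect_equal(session_loglik(agent_params(0.5, 0.5), s1), log(1/3),
               tolerance = 1e-12)
  # an action matching no feature has lapse-only mass
  s4 <- toy_session(4)
  expect_equal(session_loglik(agent_params(0.5, 0.5, lapse = 0.01), s4),
               log(0.01 / 4), tolerance = 1e-12)
  expect_error(session_loglik(agent_params(0.5, 0.5), s4),
               class = "wcst_zero_probability")
})

test_that("the vectorized grid likelihood equals the scalar replay", {
  s <- run_agent(agent_params(0.45, 0.65), task_config(n_trials = 60), seed = 61)
  g <- param_grid(7, 7)
  for (sem in c("evidence", "compact")) {
    ll_grid <- wcstbayes:::.loglik_grid(s, g$lambda, g$delta, semantics = sem)
    ll_direct <- mapply(function(l, d) {
      session_loglik(agent_params(l, d, semantics = sem), s)
    }, g$lambda, g$delta)
    expect_equal(ll_grid, unname(ll_direct), tolerance = 1e-9)
  }
})

test_that("grid posterior normalizes and reduces to the prior without data", {
  s <- run_agent(agent_params(0.5, 0.5), task_config(n_trials = 40), seed = 71)
  post <- grid_posterior(s, param_grid(21, 21))
  expect_equal(sum(post$grid$posterior), 1, tolerance = 1e-10)
  empty <- s[0, ]
  post0 <- grid_posterior(empty, param_grid(21, 21))
  expect_equal(post0$grid$posterior, rep(1 / 441, 441), tolerance = 1e-12)
})

test_that("posterior concentrates near the generating parameters", {
  s <- run_agent(agent_params(0.8, 0.3), task_config(), seed = 81)
  post <- grid_posterior(s, param_grid(51, 51))
  est <- setNames(post$summary$mean, post$summary$parameter)
  expect_lt(abs(est[["lambda"]] - 0.8), 0.35)
  expect_lt(abs(est[["delta"]] - 0.3), 0.15)
  ci <- credible_interval(post, "delta", 0.95)
  expect_lt(ci[["lower"]], ci[["upper"]])
  # tidiers
  td <- tidy(post)
  expect_equal(td$parameter, c("lambda", "delta"))
  expect_true(all(td$mean >= 0 & td$mean <= 1))
  gl <- glance(post)
  expect_equal(gl$n_trials, nrow(s))
})

test_that("posterior draws stay in bounds and follow the grid mass", {
  s <- run_agent(agent_params(0.6, 0.4), task_config(n_trials = 64), seed = 91)
  post <- grid_posterior(s, param_grid(41, 41))
  withr::with_seed(5, { d <- posterior_draws(post, 2000) })
  expect_true(all(d$lambda >= 0 & d$lambda <= 1))
  expect_true(all(d$delta >= 0 & d$delta <= 1))
  est <- setNames(post$summary$mean, post$summary$parameter)
  expect_lt(abs(mean(d$delta) - est[["delta"]]), 0.02)
})

test_that("rule annotation reconstructs the protocol and flags inconsistencies", {
  s <- run_agent(agent_params(0.7, 0.4), task_config(), seed = 95)
  stripped <- dplyr::select(tibble::as_tibble(s), "trial", "target_color",
                            "target_shape", "target_number", "action", "feedback")
  ann <- annotate_rules(stripped, task_config())
  expect_equal(ann$true_rule, s$true_rule)
  expect_equal(ann$rule_change, s$rule_change)
  bad <- stripped
  bad$feedback[5] <- 1L - bad$feedback[5]
  expect_error(annotate_rules(bad, task_config()),
               class = "wcst_inconsistent_feedback")
})

test_that("fitting an exported session round-trips the posterior", {
  s <- run_agent(agent_params(0.35, 0.6), task_config(), seed = 97)
  path <- withr::local_tempfile(fileext = ".csv")
  stripped <- dplyr::select(tibble::as_tibble(s), -"true_rule")
  write_session(stripped, path)
  fit <- fit_observed(path, config = task_config(), grid = param_grid(31, 31))
  direct <- grid_posterior(s, param_grid(31, 31), lapse = 0.01,
                           params_template = agent_params(0.5, 0.5))
  expect_equal(fit$posterior$summary, direct$summary, tolerance = 1e-10)
  expect_equal(nrow(fit$trajectories), nrow(s))
})

test_that("identifiability: recovery of delta degrades in the low range", {
  # conditional RMSE for true delta < 0.1 exceeds that for delta > 0.4,
  # assessed on the shared full-size validation study
  rec <- acceptance_recovery()
  res <- rec$results
  err <- res$delta_mean - res$delta_true
  lo <- res$delta_true < 0.1
  hi <- res$delta_true > 0.4
  expect_gte(sum(lo), 3)
  expect_gt(sqrt(mean(err[lo]^2)), sqrt(mean(err[hi]^2)))
})
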
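#' Parameter grid for the posterior over (lambda, delta)
#'
#' Equally spaced grid on the unit square with uniform prior weights,
#' matching the bivariate continuous uniform prior used for estimation.
#'
#' @param n_lambda,n_delta Number of grid nodes per parameter (default 101).
#' @return A tibble with columns `lambda`, `delta`, `prior` (weights summing
#'   to 1).
#' @export
param_grid <- function(n_lambda = 101L, n_delta = 101L) {
  g <- tidyr::expand_grid(
    lambda = seq(0, 1, length.out = n_lambda),
    delta = seq(0, 1, length.out = n_delta))
  g$prior <- 1 / nrow(g)
  g
}

#' Exact log-likelihood of a session under fixed parameters
#'
#' Replays the deterministic belief recursion conditioned on the observed
#' (action, feedback) sequence and sums the log-probabilities of the
#' observed actions under the model-implied action distribution
#' `q(a) = (1 - lapse) * sum_i predictive_i * [card_for_feature(target, i) = a]
#'  + lapse / 4`. Feedback is deterministic given actions and the protocol
#' and contributes no likelihood.
#'
#' @param params An [agent_params()] object.
#' @param session A `wcst_session` or compatible data frame.
#' @return Log-likelihood (scalar). `-Inf` is only possible with `lapse = 0`.
#' @export
session_loglik <- function(params, session) {
  session <- ensure_match_columns(session)
  sum(.replay_session(session, params)$log_q)
}

# Vectorized replay over G = length(lambda) grid nodes. omega and prior are
# G x 3 matrices updated trial by trial; returns the per-node log-likelihood.
# Mirrors .replay_session / activation_update exactly (property-tested).
.loglik_grid <- function(session, lambda, delta, lapse = 0,
                         semantics = "evidence",
                         matching_signal = "feedback",
                         activation_floor = 1e-6) {
  G <- length(lambda)
  stopifnot(length(delta) == G)
  n <- nrow(session)
  mv_all <- cbind(session$match_color, session$match_shape, session$match_number)
  feedback <- session$feedback

  omega <- matrix(0.5, G, 3)
  prior <- matrix(1 / 3, G, 3)
  ll <- numeric(G)
  ceil <- .activation_ceiling

  for (t in seq_len(n)) {
    mv <- mv_all[t, ]
    f <- feedback[t]

    q <- prior %*% mv
    q <- (1 - lapse) * q + lapse / 4
    ll <- ll + log(pmax(q, 0))

    lik <- observation_likelihood(mv, f)
    w <- prior * rep(lik, each = G)
    marg <- rowSums(w)
    post <- w / marg  # marg > 0 guaranteed by full-support predictive

    wd <- exp(delta * log(omega))  # omega^delta columnwise
    if (semantics == "compact") {
      m <- if (matching_signal == "feedback") mv * f else mv
      for (k in 1:3) {
        omega[, k] <- f * wd[, k] * m[k] +
          lambda * ((1 - f) * wd[, k] * (1 - m[k])) * omega[, k]
      }
    } else {
      for (k in 1:3) {
        if (f == 1 && mv[k] == 1) omega[, k] <- wd[, k]
        else if ((f == 1 && mv[k] == 0) || (f == 0 && mv[k] == 1)) {
          omega[, k] <- lambda * wd[, k]
        } # else: untouched
      }
    }
    omega[omega < activation_floor] <- activation_floor
    omega[omega > ceil] <- ceil

    leak <- rowSums(post * (1 - omega)) / 2
    prior <- post * (3 * omega - 1) / 2 + leak
  }
  as.numeric(ll)
}

#' Gridded posterior over (lambda, delta) for a session
#'
#' Evaluates the exact trial-wise likelihood at every grid node and combines
#' it with the uniform prior via Bayes' rule (normalized with log-sum-exp).
#' Because the belief recursion is deterministic conditioned on the observed
#' actions and feedback, the grid posterior is exact up to discretization.
#'
#' @param session A `wcst_session` or compatible data frame.
#' @param grid A [param_grid()] tibble.
#' @param lapse Response-noise weight used in the likelihood (0 for
#'   simulated sessions; use e.g. 0.01 for observed data).
#' @param params_template An [agent_params()] object supplying the update
#'   semantics and activation floor (defaults to the session's generating
#'   parameters when present, else the package defaults).
#' @return An object of class `"wcst_posterior"`: a list with `grid` (tibble
#'   with `lambda`, `delta`, `log_lik`, `posterior`), `summary` (per-parameter
#'   posterior mean, median and 95% central interval), `log_evidence`, and
#'   `n_trials`.
#' @examples
#' s <- run_agent(agent_params(0.7, 0.3), task_config(n_trials = 60), seed = 3)
#' fit <- grid_posterior(s, param_grid(41, 41))
#' tidy(fit)
#' @export
grid_posterior <- function(session, grid = param_grid(), lapse = 0,
                           params_template = attr(session, "params")) {
  if (is.null(params_template)) {
    params_template <- agent_params(0.5, 0.5)
  }
  session <- ensure_match_columns(session)
  ll <- .loglik_grid(session, grid$lambda, grid$delta, lapse = lapse,
                     semantics = params_template$semantics,
                     matching_signal = params_template$matching_signal,
                     activation_floor = params_template$activation_floor)
  lp <- ll + log(grid$prior)
  m <- max(lp)
  log_evidence <- m + log(sum(exp(lp - m)))
  post <- exp(lp - log_evidence)

  g <- tibble::tibble(lambda = grid$lambda, delta = grid$delta,
                      log_lik = ll, posterior = post)
  structure(
    list(grid = g,
         summary = .posterior_summary(g),
         log_evidence = log_evidence,
         n_trials = nrow(session),
         lapse = lapse,
         params_template = params_template),
    class = "wcst_posterior")
}

.marginal <- function(g, parameter) {
  g |>
    dplyr::group_by(value = .data[[parameter]]) |>
    dplyr::summarise(mass = sum(.data$posterior), .groups = "drop") |>
    dplyr::arrange(.data$value)
}

# Quantiles of the de-discretized marginal: each grid node is treated as a
# cell of width h (half-cells at the boundaries) carrying its mass uniformly,
# so the CDF is piecewise linear. A step-function CDF over the raw nodes
# would systematically shorten credible intervals for sharp posteriors.
.weighted_quantile <- function(value, mass, probs) {
  mass <- mass / sum(mass)
  h <- .grid_step(value)
  if (h == 0) return(rep(value[1], length(probs)))
  left <- pmax(value - h / 2, min(value))
  right <- pmin(value + h / 2, max(value))
  cdf_right <- cumsum(mass)
  cdf_left <- cdf_right - mass
  vapply(probs, function(p) {
    i <- which(cdf_right >= p - 1e-12)[1]
    if (is.na(i)) return(right[length(right)])
    frac <- (p - cdf_left[i]) / mass[i]
    left[i] + max(0, min(1, frac)) * (right[i] - left[i])
  }, numeric(1))
}

.posterior_summary <- function(g) {
  purrr::map(c("lambda", "delta"), function(par) {
    m <- .marginal(g, par)
    q <- .weighted_quantile(m$value, m$mass, c(0.025, 0.5, 0.975))
    tibble::tibble(parameter = par,
                   mean = sum(m$value * m$mass),
                   median = q[2], conf.low = q[1], conf.high = q[3])
  }) |> purrr::list_rbind()
}

#' Central credible interval from a gridded marginal posterior
#'
#' @param posterior A `wcst_posterior`.
#' @param parameter `"lambda"` or `"delta"`.
#' @param level Central probability mass (e.g. 0.9).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(posterior, parameter, level = 0.95) {
  m <- .marginal(posterior$grid, parameter)
  q <- .weighted_quantile(m$value, m$mass, c((1 - level) / 2, (1 + level) / 2))
  c(lower = q[1], upper = q[2])
}

#' @export
print.wcst_posterior <- function(x, ...) {
  cat(sprintf("<wcst_posterior> %d grid nodes, %d trials, log evidence %.2f\n",
              nrow(x$grid), x$n_trials, x$log_evidence))
  print(x$summary)
  invisible(x)
}

#' @rdname grid_posterior
#' @param x A `wcst_posterior`.
#' @param ... Unused.
#' @method tidy wcst_posterior
#' @export
tidy.wcst_posterior <- function(x, ...) {
  x$summary
}

#' @rdname grid_posterior
#' @method glance wcst_posterior
#' @export
glance.wcst_posterior <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    nodes = nrow(x$grid),
    log_evidence = x$log_evidence,
    lambda_mean = x$summary$mean[x$summary$parameter == "lambda"],
    delta_mean = x$summary$mean[x$summary$parameter == "delta"])
}

#' Draw parameter values from a gridded posterior
#'
#' Samples grid nodes proportionally to their posterior mass and jitters each
#' draw uniformly within its grid cell, de-discretizing the posterior (used
#' for simulation-based calibration ranks).
#'
#' @param posterior A `wcst_posterior`.
#' @param n Number of draws.
#' @return A tibble with columns `lambda`, `delta`.
#' @export
posterior_draws <- function(posterior, n) {
  g <- posterior$grid
  h_l <- .grid_step(g$lambda); h_d <- .grid_step(g$delta)
  idx <- sample.int(nrow(g), n, replace = TRUE, prob = g$posterior)
  # jitter within the (boundary-truncated) cell of each node, matching the
  # piecewise-linear CDF used for quantiles
  jitter_in_cell <- function(v, h) {
    lo <- pmax(v - h / 2, 0); hi <- pmin(v + h / 2, 1)
    stats::runif(length(v), lo, hi)
  }
  tibble::tibble(
    lambda = jitter_in_cell(g$lambda[idx], h_l),
    delta = jitter_in_cell(g$delta[idx], h_d))
}

.grid_step <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(0)
  min(diff(u))
}

#' Fit the model to an observed session log
#'
#' Reads a session log (CSV file or data frame) without true-rule
#' annotations, reconstructs the rule sequence from the feedback stream and
#' the Heaton protocol (the rule advances after each run of
#' `consecutive_to_complete` correct responses, cycling through
#' `rule_sequence`), verifies that the feedback stream is consistent with the
#' reconstruction, fits the gridded posterior, and reconstructs
#' information-theoretic trajectories at the posterior mean.
#'
#' @param x Path to a session CSV (see [read_session()]) or a session data
#'   frame.
#' @param config The protocol [task_config()] (default: 128 trials, 6
#'   categories, color-shape-number cycle).
#' @param grid A [param_grid()].
#' @param lapse Response-noise weight for the likelihood (default 0.01 so
#'   that responses matching no feature have positive likelihood).
#' @param params_template Semantics template, see [grid_posterior()].
#' @return A list with `posterior` (a `wcst_posterior`), `trajectories`
#'   (a `wcst_trajectory` at the posterior mean), and `session` (the
#'   annotated session).
#' @export
fit_observed <- function(x,
                         config = task_config(max_categories = 6),
                         grid = param_grid(),
                         lapse = 0.01,
                         params_template = NULL) {
  session <- if (is.character(x)) read_session(x) else tibble::as_tibble(x)
  session <- ensure_match_columns(session)
  session <- annotate_rules(session, config)
  if (is.null(params_template)) params_template <- agent_params(0.5, 0.5)
  post <- grid_posterior(session, grid, lapse = lapse,
                         params_template = params_template)
  est <- setNames(post$summary$mean, post$summary$parameter)
  params_hat <- agent_params(est[["lambda"]], est[["delta"]], lapse = lapse,
                             activation_floor = params_template$activation_floor,
                             semantics = params_template$semantics,
                             matching_signal = params_template$matching_signal)
  traj <- reconstruct_trajectories(session, params_hat)
  list(posterior = post, trajectories = traj, session = session)
}

#' Reconstruct true-rule annotations from feedback under the protocol
#'
#' @inheritParams fit_observed
#' @param session Session data frame with targets, actions and feedback.
#' @return The session with `true_rule` and `rule_change` columns added.
#' @export
annotate_rules <- function(session, config = task_config()) {
  session <- ensure_match_columns(session)
  mv <- cbind(session$match_color, session$match_shape, session$match_number)
  n <- nrow(session)
  rule_pos <- 1L
  rule <- config$rule_sequence[1L]
  streak <- 0L
  true_rule <- integer(n); rule_change <- logical(n)
  for (t in seq_len(n)) {
    expected <- mv[t, rule]
    if (!is.na(session$feedback[t]) && session$feedback[t] != expected) {
      rlang::abort(sprintf(
        paste0("Feedback at trial %d is inconsistent with the protocol ",
               "(rule %s implies feedback %d, observed %d). ",
               "Check the protocol configuration."),
        t, .wcst_features[rule], expected, session$feedback[t]),
        class = "wcst_inconsistent_feedback")
    }
    true_rule[t] <- rule
    if (session$feedback[t] == 1) streak <- streak + 1L else streak <- 0L
    if (streak == config$consecutive_to_complete) {
      rule_pos <- rule_pos %% length(config$rule_sequence) + 1L
      rule <- config$rule_sequence[rule_pos]
      streak <- 0L
      rule_change[t] <- TRUE
    }
  }
  session$true_rule <- true_rule
  session$rule_change <- rule_change
  session
}
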
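#' Cognitive parameters of the Bayesian WCST agent
#'
#' The agent is governed by two parameters on the unit interval. Flexibility
#' `lambda` scales the activation retained by features that the current
#' feedback disconfirms: high flexibility keeps competing rules available for
#' rapid set-shifting, low flexibility lets their activation decay towards
#' the fixed point `lambda^(1/(1-delta))`, producing a drift of the
#' predictive distribution back towards previously valid rules and hence
#' perseveration. Information loss `delta` is the exponent of the
#' multiplicative activation rescaling `omega^delta`: at `delta = 0` a single
#' confirmation saturates the activation of the confirmed feature, while
#' larger values slow the convergence of the internal model to the true task
#' model.
#'
#' @param lambda Flexibility, in \[0, 1\].
#' @param delta Information loss, in \[0, 1\].
#' @param lapse Response-noise mixture weight in \[0, 1): with probability
#'   `lapse` the action is uniform over the four cards. Default 0 for
#'   simulation; use a small positive value (0.01) when fitting observed
#'   data so that responses matching no feature retain positive likelihood.
#' @param activation_floor Lower clamp for activations after each update
#'   (default `1e-6`); a symmetric upper clamp at `1 - 1e-15` keeps the
#'   predictive distribution on full support.
#' @param semantics Activation-update semantics. `"evidence"` (default)
#'   applies the delta-rescaled update to the features the feedback bears
#'   evidence on: confirmed features get `omega^delta`, disconfirmed features
#'   get `lambda * omega^delta`, untouched features keep their activation.
#'   `"compact"` is the literal compact update
#'   `f * omega^delta * m + lambda * ((1 - f) * omega^delta * (1 - m)) * omega`.
#' @param matching_signal Gating of the matching signal `m_t` used by the
#'   `"compact"` semantics: `"feedback"` (default) sets `m_t` to the match
#'   vector on positive feedback and to zero otherwise; `"always"` sets
#'   `m_t` to the match vector regardless of feedback.
#' @return A list of class `"wcst_params"`.
#' @examples
#' agent_params(lambda = 0.9, delta = 0.4)
#' @export
agent_params <- function(lambda, delta, lapse = 0,
                         activation_floor = 1e-6,
                         semantics = c("evidence", "compact"),
                         matching_signal = c("feedback", "always")) {
  semantics <- match.arg(semantics)
  matching_signal <- match.arg(matching_signal)
  stopifnot(length(lambda) == 1, length(delta) == 1)
  if (is.na(lambda) || lambda < 0 || lambda > 1) rlang::abort("`lambda` must be in [0, 1].")
  if (is.na(delta) || delta < 0 || delta > 1) rlang::abort("`delta` must be in [0, 1].")
  if (is.na(lapse) || lapse < 0 || lapse >= 1) rlang::abort("`lapse` must be in [0, 1).")
  if (activation_floor <= 0 || activation_floor >= 0.5) {
    rlang::abort("`activation_floor` must be a small positive number below 0.5.")
  }
  structure(
    list(lambda = as.numeric(lambda), delta = as.numeric(delta),
         lapse = as.numeric(lapse),
         activation_floor = as.numeric(activation_floor),
         semantics = semantics, matching_signal = matching_signal),
    class = "wcst_params")
}

#' @export
print.wcst_params <- function(x, ...) {
  cat(sprintf("<wcst_params> lambda = %.3f, delta = %.3f, lapse = %.3f (%s semantics)\n",
              x$lambda, x$delta, x$lapse, x$semantics))
  invisible(x)
}

# upper clamp: keeps stability-matrix off-diagonals strictly positive so the
# predictive distribution never loses support entirely
.activation_ceiling <- 1 - 1e-15

#' Likelihood of a response-feedback observation under each candidate rule
#'
#' Component i is the likelihood of the observation `(action, feedback)`
#' assuming the current rule is feature i, with the matching probability
#' taken as the 0/1 indicator that the chosen card matches the target on
#' feature i:
#' `(f * m_i + (1 - f) * (1 - m_i)) / (f * sum(m) + (1 - f) * sum(1 - m))`.
#' The result is non-negative but not, in general, a probability vector
#' over i.
#'
#' @param match Binary match vector of length 3 (see [match_vector()]).
#' @param feedback 0 or 1.
#' @return Numeric vector of length 3.
#' @examples
#' observation_likelihood(c(1, 0, 0), 1)  # (1, 0, 0)
#' observation_likelihood(c(1, 0, 0), 0)  # (0, 1/2, 1/2)
#' @export
observation_likelihood <- function(match, feedback) {
  match <- as.numeric(match)
  stopifnot(length(match) == 3, feedback %in% c(0, 1))
  num <- feedback * match + (1 - feedback) * (1 - match)
  den <- sum(num)
  if (den == 0) {
    rlang::abort(paste0(
      "Impossible observation: positive feedback for a card matching the ",
      "target on no feature. Use a positive `lapse` when fitting observed data."),
      class = "wcst_impossible_observation")
  }
  num / den
}

#' Bayesian belief update
#'
#' @param prior Probability vector over the three rules.
#' @param likelihood Non-negative likelihood vector (see
#'   [observation_likelihood()]).
#' @return A list with `posterior` (normalized) and `marginal`, the
#'   predictive probability of the observation
#'   `sum(likelihood * prior)` consumed by the Shannon surprise.
#' @export
posterior_update <- function(prior, likelihood) {
  w <- likelihood * prior
  marginal <- sum(w)
  if (marginal <= 0) {
    rlang::abort(paste0(
      "Zero-probability observation under the current beliefs; ",
      "use a positive `lapse` when fitting observed data."),
      class = "wcst_zero_probability")
  }
  list(posterior = w / marginal, marginal = marginal)
}

#' Matching signal
#'
#' The matching signal marks the features the feedback flags as currently
#' relevant. Under the default feedback gating it equals the match vector on
#' positive feedback and is zero otherwise; under `"always"` it equals the
#' match vector regardless of feedback.
#'
#' @inheritParams observation_likelihood
#' @param gating `"feedback"` or `"always"`.
#' @return Integer vector of length 3.
#' @export
matching_signal <- function(match, feedback, gating = c("feedback", "always")) {
  gating <- match.arg(gating)
  match <- as.integer(match)
  if (gating == "feedback" && feedback == 0) return(c(0L, 0L, 0L))
  match
}

#' Activation update
#'
#' Updates the state-activation vector from the observed match vector and
#' feedback. See [agent_params()] for the two available semantics. The result
#' is clamped to `[activation_floor, 1 - 1e-15]`.
#'
#' @param omega Current activation vector (length 3, in (0, 1\]).
#' @param match Binary match vector.
#' @param feedback 0 or 1.
#' @param params An [agent_params()] object.
#' @return Updated activation vector.
#' @examples
#' p <- agent_params(0.5, 0, semantics = "compact")
#' activation_update(c(.5, .5, .5), c(1, 0, 0), 1, p)
#' @export
activation_update <- function(omega, match, feedback, params) {
  w <- as.numeric(omega)
  m01 <- as.numeric(match)
  lam <- params$lambda
  del <- params$delta
  if (params$semantics == "compact") {
    m <- as.numeric(matching_signal(m01, feedback, params$matching_signal))
    out <- feedback * w^del * m +
      lam * ((1 - feedback) * w^del * (1 - m)) * w
  } else {
    # evidence semantics: the feedback confirms matched features when f = 1
    # and disconfirms them when f = 0; unmatched features are disconfirmed by
    # positive feedback (the rule must be among the matched features) and
    # untouched by negative feedback (no evidence about them)
    out <- w
    confirmed <- feedback == 1 & m01 == 1
    disconfirmed <- if (feedback == 1) m01 == 0 else m01 == 1
    out[confirmed] <- w[confirmed]^del
    out[disconfirmed] <- lam * w[disconfirmed]^del
  }
  pmin(pmax(out, params$activation_floor), .activation_ceiling)
}

#' Stability matrix
#'
#' Row-stochastic transition matrix encoding the agent's belief about rule
#' persistence: diagonal entries are the activations, off-diagonal entries
#' split the complement evenly, `(1 - omega_i) / 2`.
#'
#' @param omega Activation vector (length 3, in \[0, 1\]).
#' @return A 3 x 3 matrix with rows summing to 1 and diagonal `omega`.
#' @export
stability_matrix <- function(omega) {
  omega <- as.numeric(omega)
  stopifnot(length(omega) == 3)
  off <- (1 - omega) / 2
  G <- matrix(rep(off, each = 3), nrow = 3, byrow = TRUE)
  diag(G) <- omega
  G
}

#' Predictive (Chapman-Kolmogorov) update
#'
#' Propagates the posterior through the stability matrix:
#' `predictive_k = sum_i Gamma_ik * posterior_i`.
#'
#' @param posterior Probability vector over the three rules.
#' @param stability A 3 x 3 row-stochastic matrix (see [stability_matrix()]).
#' @return Probability vector over the three rules (the prior for the next
#'   trial).
#' @export
predictive_update <- function(posterior, stability) {
  as.numeric(crossprod(stability, as.numeric(posterior)))
}

# fast predictive update used in the hot loops: algebraic form of
# t(Gamma) %*% post for the Eq.-4 structure
.predictive_fast <- function(posterior, omega) {
  leak <- sum(posterior * (1 - omega)) / 2
  posterior * (3 * omega - 1) / 2 + leak
}

#' Sample an action from the predictive internal model
#'
#' With probability `1 - lapse` a feature is sampled from the predictive
#' distribution and the card matching the target on that feature is chosen;
#' with probability `lapse` the card is uniform over the four alternatives.
#' Uses the current RNG state.
#'
#' @param predictive Probability vector over the three rules.
#' @param target Target card (see [match_vector()]).
#' @param lapse Response-noise weight in \[0, 1).
#' @return A list with `feature` (sampled feature index) and `action`
#'   (card index).
#' @export
sample_action <- function(predictive, target, lapse = 0) {
  target <- .as_target(target)
  feature <- sample.int(3L, 1L, prob = predictive)
  if (lapse > 0 && stats::runif(1) < lapse) {
    action <- sample.int(4L, 1L)
  } else {
    action <- which(.deck_matrix[, feature] == target[feature])
  }
  list(feature = feature, action = action)
}

#' Closed-form action distribution implied by the model
#'
#' The probability of choosing each of the four cards given the predictive
#' distribution over rules, the target, and the lapse rate:
#' `q(a) = (1 - lapse) * sum_i predictive_i * [card_for_feature(target, i) = a]
#'  + lapse / 4`.
#'
#' @inheritParams sample_action
#' @return Numeric vector of length 4 summing to 1.
#' @export
action_distribution <- function(predictive, target, lapse = 0) {
  target <- .as_target(target)
  q <- numeric(4)
  for (i in 1:3) {
    a <- which(.deck_matrix[, i] == target[i])
    q[a] <- q[a] + predictive[i]
  }
  (1 - lapse) * q + lapse / 4
}

#' Simulate a full WCST session
#'
#' Runs the generative loop: initialize activations at (0.5, 0.5, 0.5) and a
#' uniform prior over rules; each trial, sample an action from the predictive
#' internal model, obtain feedback from the task environment, update the
#' posterior, the activations, the stability matrix and the predictive
#' distribution.
#'
#' @param params An [agent_params()] object.
#' @param config A [task_config()] object.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   sessions.
#' @return A tibble of class `"wcst_session"`, one row per trial, with the
#'   trial record (target features, action, feedback, true rule, sampled
#'   feature, match vector, category bookkeeping) and belief snapshots
#'   (`prior_*`, `posterior_*`, `omega_*`, `marginal`). Attributes `params`,
#'   `config` and `seed` carry the generating configuration.
#' @examples
#' s <- run_agent(agent_params(0.9, 0.4), task_config(n_trials = 30), seed = 1)
#' head(s)
#' @export
run_agent <- function(params, config = task_config(), seed = NULL) {
  stopifnot(inherits(params, "wcst_params"), inherits(config, "wcst_config"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_agent(params, config, seed = NULL)))
  }

  n <- config$n_trials
  targets <- draw_targets(n, config$deck_policy, config$targets)
  tc <- as.integer(targets$color); ts <- as.integer(targets$shape)
  tn <- as.integer(targets$number)

  omega <- c(0.5, 0.5, 0.5)
  prior <- rep(1 / 3, 3)
  rule_pos <- 1L
  rule <- config$rule_sequence[1L]
  streak <- 0L
  categories <- 0L

  action <- integer(n); feedback <- integer(n); true_rule <- integer(n)
  sampled <- integer(n); rule_change <- logical(n)
  match_m <- matrix(0L, n, 3)
  prior_m <- matrix(0, n, 3); post_m <- matrix(0, n, 3); omega_m <- matrix(0, n, 3)
  marginal <- numeric(n)

  deck <- .deck_matrix
  lapse <- params$lapse
  n_done <- 0L

  for (t in seq_len(n)) {
    tgt <- c(tc[t], ts[t], tn[t])
    feat <- sample.int(3L, 1L, prob = prior)
    if (lapse > 0 && stats::runif(1) < lapse) {
      a <- sample.int(4L, 1L)
    } else {
      a <- which(deck[, feat] == tgt[feat])
    }
    mv <- as.integer(deck[a, ] == tgt)
    f <- mv[rule]

    lik <- observation_likelihood(mv, f)
    up <- posterior_update(prior, lik)
    omega <- activation_update(omega, mv, f, params)

    prior_m[t, ] <- prior
    post_m[t, ] <- up$posterior
    omega_m[t, ] <- omega
    marginal[t] <- up$marginal
    action[t] <- a; feedback[t] <- f; true_rule[t] <- rule
    sampled[t] <- feat; match_m[t, ] <- mv

    prior <- .predictive_fast(up$posterior, omega)
    n_done <- t

    if (f == 1L) streak <- streak + 1L else streak <- 0L
    if (streak == config$consecutive_to_complete) {
      rule_pos <- rule_pos %% length(config$rule_sequence) + 1L
      rule <- config$rule_sequence[rule_pos]
      streak <- 0L
      categories <- categories + 1L
      rule_change[t] <- TRUE
      if (categories >= config$max_categories) break
    }
  }

  idx <- seq_len(n_done)
  out <- tibble::tibble(
    trial = idx,
    target_color = tc[idx], target_shape = ts[idx], target_number = tn[idx],
    action = action[idx], feedback = feedback[idx], true_rule = true_rule[idx],
    sampled_feature = sampled[idx], rule_change = rule_change[idx],
    match_color = match_m[idx, 1], match_shape = match_m[idx, 2],
    match_number = match_m[idx, 3],
    prior_1 = prior_m[idx, 1], prior_2 = prior_m[idx, 2], prior_3 = prior_m[idx, 3],
    posterior_1 = post_m[idx, 1], posterior_2 = post_m[idx, 2],
    posterior_3 = post_m[idx, 3],
    omega_1 = omega_m[idx, 1], omega_2 = omega_m[idx, 2], omega_3 = omega_m[idx, 3],
    marginal = marginal[idx]
  )
  new_wcst_session(out, params = params, config = config, seed = seed)
}

new_wcst_session <- function(data, params = NULL, config = NULL, seed = NULL) {
  structure(data,
            class = c("wcst_session", class(tibble::tibble()))) |>
    (\(x) { attr(x, "params") <- params; attr(x, "config") <- config
            attr(x, "seed") <- seed; x })()
}

#' @export
print.wcst_session <- function(x, ...) {
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf("# WCST session: %d trials (lambda = %.2f, delta = %.2f)\n",
                nrow(x), p$lambda, p$delta))
  } else {
    cat(sprintf("# WCST session: %d trials\n", nrow(x)))
  }
  NextMethod()
}
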
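#' Bayesian surprise
#'
#' Kullback-Leibler divergence, in nats, between the updated predictive
#' distribution for the next trial and the predictive (prior) distribution
#' that was held for the current trial:
#' `KL(p(s_{t+1} | x_{0:t}) || p(s_t | x_{0:t-1}))`. Quantifies the magnitude
#' of the belief update caused by the trial's observation.
#'
#' @param predictive_next Probability vector over rules after the update.
#' @param prior_current Probability vector held before the update.
#' @return Non-negative divergence in nats (`0 * log(0/q)` taken as 0).
#' @examples
#' bayesian_surprise(c(.25, .375, .375), rep(1/3, 3))
#' @export
bayesian_surprise <- function(predictive_next, prior_current) {
  p <- as.numeric(predictive_next); q <- as.numeric(prior_current)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz])))
}

#' Shannon surprise
#'
#' Conditional information content, in nats, of the trial's observation:
#' `-log p(x_t | x_{0:t-1})`, with the marginal taken from
#' [posterior_update()].
#'
#' @param marginal Predictive probability of the observation, in (0, 1\].
#' @return Non-negative surprise in nats.
#' @export
shannon_surprise <- function(marginal) {
  -log(as.numeric(marginal))
}

#' Predictive entropy
#'
#' Shannon entropy, in nats, of the predictive distribution over the three
#' rules; the agent's epistemic uncertainty about the current rule, bounded
#' by `log(3)`.
#'
#' @param predictive Probability vector over the three rules.
#' @return Entropy in `[0, log(3)]` nats (`0 * log 0` taken as 0).
#' @export
predictive_entropy <- function(predictive) {
  p <- as.numeric(predictive)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Deterministic replay of the belief recursion conditioned on the observed
# (action, feedback) sequence of a session. Returns per-trial prior,
# posterior, omega, marginal, per-trial action log-probability, and the
# predictive distribution following the last trial.
.replay_session <- function(session, params) {
  n <- nrow(session)
  mv_all <- cbind(session$match_color, session$match_shape, session$match_number)
  feedback <- session$feedback
  action <- session$action
  tgt_all <- cbind(session$target_color, session$target_shape, session$target_number)

  omega <- c(0.5, 0.5, 0.5)
  prior <- rep(1 / 3, 3)
  prior_m <- matrix(0, n, 3); post_m <- matrix(0, n, 3); omega_m <- matrix(0, n, 3)
  marginal <- numeric(n); log_q <- numeric(n)
  lapse <- params$lapse
  deck <- .deck_matrix

  for (t in seq_len(n)) {
    mv <- mv_all[t, ]
    q <- 0
    for (i in 1:3) if (mv[i] == 1L) q <- q + prior[i]
    q <- (1 - lapse) * q + lapse / 4
    if (q <= 0) {
      rlang::abort(paste0(
        "Observed action has zero probability under the model at trial ", t,
        "; refit with `lapse > 0`."), class = "wcst_zero_probability")
    }
    log_q[t] <- log(q)

    lik <- observation_likelihood(mv, feedback[t])
    up <- posterior_update(prior, lik)
    omega <- activation_update(omega, mv, feedback[t], params)

    prior_m[t, ] <- prior
    post_m[t, ] <- up$posterior
    omega_m[t, ] <- omega
    marginal[t] <- up$marginal
    prior <- .predictive_fast(up$posterior, omega)
  }
  list(prior = prior_m, posterior = post_m, omega = omega_m,
       marginal = marginal, log_q = log_q, predictive_final = prior)
}

#' Reconstruct information-theoretic trajectories from a session
#'
#' Replays the deterministic belief recursion conditioned on the observed
#' (action, feedback) sequence under the supplied parameters (e.g. posterior
#' means from [grid_posterior()]) and returns the per-trial Bayesian
#' surprise, Shannon surprise and predictive entropy. Applied to a simulated
#' session with its generating parameters, the replayed beliefs equal the
#' simulation-time logs exactly.
#'
#' @param session A `wcst_session` (or any data frame with the session
#'   columns: targets, `action`, `feedback`, match vector).
#' @param params An [agent_params()] object; defaults to the session's
#'   generating parameters when present.
#' @return A tibble of class `"wcst_trajectory"` with columns `trial`,
#'   `bayesian_surprise`, `shannon_surprise`, `entropy` (all in nats).
#' @examples
#' s <- run_agent(agent_params(0.9, 0.1), task_config(n_trials = 40), seed = 2)
#' reconstruct_trajectories(s)
#' @export
reconstruct_trajectories <- function(session, params = attr(session, "params")) {
  if (is.null(params)) {
    rlang::abort("`params` must be supplied for sessions without generating parameters.")
  }
  session <- ensure_match_columns(session)
  rep <- .replay_session(session, params)
  n <- nrow(session)
  # predictive held at trial t is prior[t, ]; predictive after trial t is
  # prior[t + 1, ] (or the final predictive for the last trial)
  pred_next <- rbind(rep$prior[-1, , drop = FALSE], rep$predictive_final)
  traj <- tibble::tibble(
    trial = session$trial,
    bayesian_surprise = vapply(
      seq_len(n), function(t) bayesian_surprise(pred_next[t, ], rep$prior[t, ]),
      numeric(1)),
    shannon_surprise = shannon_surprise(rep$marginal),
    entropy = vapply(seq_len(n), function(t) predictive_entropy(rep$prior[t, ]),
                     numeric(1))
  )
  class(traj) <- c("wcst_trajectory", class(tibble::tibble()))
  traj
}

# recompute the match vector columns from targets and actions if absent
ensure_match_columns <- function(session) {
  need <- c("match_color", "match_shape", "match_number")
  if (all(need %in% names(session))) return(session)
  mv <- t(vapply(seq_len(nrow(session)), function(t) {
    match_vector(c(session$target_color[t], session$target_shape[t],
                   session$target_number[t]), session$action[t])
  }, integer(3)))
  session$match_color <- mv[, 1]; session$match_shape <- mv[, 2]
  session$match_number <- mv[, 3]
  session
}
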
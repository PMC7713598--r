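# Shared helpers: toy-session construction and an independent vectorized
# simulator used as the rejection-ABC oracle.

# Target (1, 2, 3) makes every stimulus card an unambiguous (or null) match:
# card 1 matches color only, card 2 shape only, card 3 number only, card 4
# nothing.
toy_target <- c(color = 1L, shape = 2L, number = 3L)

# Build an annotated session from a vector of chosen actions under a given
# rule schedule (10-consecutive advancement, color -> shape -> number).
toy_session <- function(actions, consecutive = 10L) {
  n <- length(actions)
  rule_seq <- c(1L, 2L, 3L)
  rule <- 1L; pos <- 1L; streak <- 0L
  feedback <- integer(n); true_rule <- integer(n); rule_change <- logical(n)
  mv <- matrix(0L, n, 3)
  for (t in seq_len(n)) {
    m <- match_vector(toy_target, actions[t])
    mv[t, ] <- m
    true_rule[t] <- rule
    feedback[t] <- m[rule]
    streak <- if (feedback[t] == 1) streak + 1L else 0L
    if (streak == consecutive) {
      pos <- pos %% 3L + 1L; rule <- rule_seq[pos]; streak <- 0L
      rule_change[t] <- TRUE
    }
  }
  tibble::tibble(
    trial = seq_len(n),
    target_color = toy_target[[1]], target_shape = toy_target[[2]],
    target_number = toy_target[[3]],
    action = as.integer(actions), feedback = feedback, true_rule = true_rule,
    rule_change = rule_change,
    match_color = mv[, 1], match_shape = mv[, 2], match_number = mv[, 3])
}

# Independent vectorized re-implementation of the generative model
# ("evidence" semantics), simulating n_rep sessions in parallel on a fixed
# target list. Used as the rejection-ABC oracle; shares no code with the
# package internals.
abc_simulate_actions <- function(n_rep, targets, lambda, delta,
                                 consecutive = 10L, floor = 1e-6,
                                 ceiling = 1 - 1e-15) {
  deck <- as.matrix(stimulus_deck()[, c("color", "shape", "number")])
  n_trials <- nrow(targets)
  omega <- matrix(0.5, n_rep, 3)
  prior <- matrix(1 / 3, n_rep, 3)
  rule <- rep(1L, n_rep); pos <- rep(1L, n_rep); streak <- rep(0L, n_rep)
  actions <- matrix(0L, n_rep, n_trials)
  for (t in seq_len(n_trials)) {
    tgt <- as.integer(targets[t, c("color", "shape", "number")])
    # card matching the target on each feature dimension
    card_of <- vapply(1:3, function(i) which(deck[, i] == tgt[i]), integer(1))
    u <- stats::runif(n_rep)
    cdf1 <- prior[, 1]; cdf2 <- prior[, 1] + prior[, 2]
    feat <- 1L + (u > cdf1) + (u > cdf2)
    a <- card_of[feat]
    actions[, t] <- a
    match <- t(vapply(1:4, function(card) as.integer(deck[card, ] == tgt),
                      integer(3)))[a, , drop = FALSE]
    f <- match[cbind(seq_len(n_rep), rule)]
    # likelihood and posterior
    lik_pos <- match / rowSums(match)
    lik_neg <- (1 - match) / rowSums(1 - match)
    lik <- lik_pos * f + lik_neg * (1 - f)
    w <- prior * lik
    post <- w / rowSums(w)
    # activation: confirmed ^delta, disconfirmed lambda * ^delta, else keep
    wd <- omega^delta
    confirmed <- (f == 1) * match
    disconfirmed <- (f == 1) * (1 - match) + (1 - f) * match
    omega <- confirmed * wd + disconfirmed * lambda * wd +
      (1 - confirmed - disconfirmed) * omega
    omega[omega < floor] <- floor
    omega[omega > ceiling] <- ceiling
    leak <- rowSums(post * (1 - omega)) / 2
    prior <- post * (3 * omega - 1) / 2 + leak
    # task bookkeeping
    streak <- ifelse(f == 1, streak + 1L, 0L)
    adv <- streak == consecutive
    pos <- ifelse(adv, pos %% 3L + 1L, pos)
    rule <- ifelse(adv, c(1L, 2L, 3L)[pos], rule)
    streak[adv] <- 0L
  }
  actions
}

# Shared expensive computations, cached across test files in one run.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_factorial <- function() {
  if (is.null(.acceptance_cache$factorial)) {
    scores <- run_factorial(n_agents = 150, seed = 20260922)
    .acceptance_cache$factorial <- summarize_factorial(scores)
  }
  .acceptance_cache$factorial
}

acceptance_recovery <- function() {
  if (is.null(.acceptance_cache$recovery)) {
    .acceptance_cache$recovery <- recovery_study(n_sets = 300, seed = 20260923)
  }
  .acceptance_cache$recovery
}

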
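#' Classify each trial of a session as correct, perseverative or other error
#'
#' A "perseverated-to principle" is maintained as the rule that was in force
#' before the most recent rule change (undefined before the first change).
#' An error trial is perseverative when the chosen card is consistent with
#' sorting by that principle. Three operationalizations are available:
#'
#' * `"principle"` (default): any error whose chosen card matches the target
#'   on the perseverated-to principle counts as perseverative, whether or not
#'   the response is ambiguous.
#' * `"unambiguous"`: only errors matching the perseverated-to principle and
#'   no other dimension count.
#' * `"sandwich"`: as `"unambiguous"`, with ambiguous principle-matching
#'   errors additionally counted when they occur between two unambiguous
#'   perseverative errors.
#'
#' Errors before the first rule change are non-perseverative under all rules.
#'
#' @param session A `wcst_session` (must carry `true_rule` annotations and
#'   the `rule_change` flag, as simulated sessions do; see [fit_observed()]
#'   for protocol-based reconstruction of observed data).
#' @param pe_rule Perseveration criterion, see above.
#' @return The session with an added factor column `response_type` with
#'   levels `correct`, `perseverative`, `other_error`.
#' @export
classify_errors <- function(session,
                            pe_rule = c("principle", "unambiguous", "sandwich")) {
  pe_rule <- match.arg(pe_rule)
  if (!"true_rule" %in% names(session) || anyNA(session$true_rule)) {
    rlang::abort("`session` must carry true-rule annotations to score perseveration.")
  }
  session <- ensure_match_columns(session)
  session <- ensure_rule_change(session)
  n <- nrow(session)
  mv <- cbind(session$match_color, session$match_shape, session$match_number)
  err <- session$feedback == 0

  principle <- rep(NA_integer_, n)
  cur <- NA_integer_
  for (t in seq_len(n)) {
    principle[t] <- cur
    if (isTRUE(session$rule_change[t])) cur <- session$true_rule[t]
  }

  matches_principle <- !is.na(principle) &
    mv[cbind(seq_len(n), ifelse(is.na(principle), 1L, principle))] == 1
  unambiguous <- rowSums(mv) == 1

  pe <- switch(pe_rule,
    principle = err & matches_principle,
    unambiguous = err & matches_principle & unambiguous,
    sandwich = {
      base <- err & matches_principle & unambiguous
      amb <- which(err & matches_principle & !unambiguous)
      for (i in amb) {
        if (any(base[seq_len(i - 1)]) && any(base[seq(i, n) [-1]])) base[i] <- TRUE
      }
      base
    })

  session$response_type <- factor(
    ifelse(!err, "correct", ifelse(pe, "perseverative", "other_error")),
    levels = c("correct", "perseverative", "other_error"))
  session
}

# derive the rule_change flag from the true_rule sequence when absent
ensure_rule_change <- function(session) {
  if ("rule_change" %in% names(session)) return(session)
  r <- session$true_rule
  session$rule_change <- c(r[-1] != r[-length(r)], FALSE)
  session
}

#' Trials to complete the first category
#'
#' Index of the trial completing the first run of
#' `consecutive_to_complete` correct responses; censored at the session
#' length when no category is completed.
#'
#' @param session A session data frame with a `feedback` column.
#' @param consecutive_to_complete Run length defining category completion
#'   (default from the session's config, else 10).
#' @return A one-row tibble with columns `trials` and `censored`.
#' @export
trials_to_first_category <- function(session, consecutive_to_complete = NULL) {
  if (is.null(consecutive_to_complete)) {
    cfg <- attr(session, "config")
    consecutive_to_complete <- if (!is.null(cfg)) cfg$consecutive_to_complete else 10L
  }
  streak <- 0L
  for (t in seq_len(nrow(session))) {
    streak <- if (session$feedback[t] == 1) streak + 1L else 0L
    if (streak == consecutive_to_complete) {
      return(tibble::tibble(trials = t, censored = FALSE))
    }
  }
  tibble::tibble(trials = nrow(session), censored = TRUE)
}

#' Failures to maintain set
#'
#' Counts errors that directly follow at least `acquisition` consecutive
#' correct responses under the same, still-incomplete category: the sorting
#' principle had demonstrably been acquired, and the error reflects
#' distractibility rather than set-shifting. The streak resets at rule
#' changes, so errors following a completed category are not counted.
#'
#' @inheritParams trials_to_first_category
#' @param acquisition Streak length defining acquisition of the set
#'   (default 5).
#' @return Integer count.
#' @export
failures_to_maintain_set <- function(session, acquisition = 5L) {
  session <- ensure_rule_change(session)
  fms <- 0L
  streak <- 0L
  for (t in seq_len(nrow(session))) {
    if (session$feedback[t] == 0) {
      if (streak >= acquisition) fms <- fms + 1L
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (isTRUE(session$rule_change[t])) streak <- 0L
    }
  }
  fms
}

#' Heaton-style clinical score report for a session
#'
#' Aggregates total, perseverative and non-perseverative errors, trials to
#' first category (with censoring flag), failures to maintain set, and
#' completed categories into a one-row tibble.
#'
#' @inheritParams classify_errors
#' @return A one-row tibble with columns `total_errors`,
#'   `perseverative_errors`, `other_errors`, `trials_to_first_category`,
#'   `tfc_censored`, `failures_to_maintain_set`, `categories_completed`.
#' @examples
#' s <- run_agent(agent_params(0.3, 0.4), seed = 7)
#' score_session(s)
#' @export
score_session <- function(session,
                          pe_rule = c("principle", "unambiguous", "sandwich")) {
  cls <- classify_errors(session, pe_rule)
  tfc <- trials_to_first_category(session)
  tibble::tibble(
    total_errors = sum(cls$response_type != "correct"),
    perseverative_errors = sum(cls$response_type == "perseverative"),
    other_errors = sum(cls$response_type == "other_error"),
    trials_to_first_category = tfc$trials,
    tfc_censored = tfc$censored,
    failures_to_maintain_set = failures_to_maintain_set(session),
    categories_completed = sum(cls$rule_change)
  )
}
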
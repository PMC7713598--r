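#' The four canonical WCST stimulus cards
#'
#' The Heaton-style WCST uses four stimulus cards that are pairwise distinct
#' on every feature dimension: one red triangle, two green stars, three yellow
#' crosses, four blue circles. Distinctness guarantees that for any target
#' card and any feature dimension there is exactly one stimulus card matching
#' the target on that dimension.
#'
#' Feature values are coded 1..4: color (1 red, 2 green, 3 blue, 4 yellow),
#' shape (1 triangle, 2 star, 3 cross, 4 circle), number (1..4 objects).
#'
#' @return A tibble with columns `card`, `color`, `shape`, `number`
#'   (one row per stimulus card).
#' @examples
#' stimulus_deck()
#' @export
stimulus_deck <- function() {
  tibble::tibble(
    card = 1:4,
    color = c(1L, 2L, 4L, 3L),   # red, green, yellow, blue
    shape = c(1L, 2L, 3L, 4L),   # triangle, star, cross, circle
    number = c(1L, 2L, 3L, 4L)
  )
}

# 4 x 3 integer matrix of stimulus-card features, rows = cards,
# cols = color/shape/number; kept as a constant for the hot simulation loop
.deck_matrix <- matrix(
  c(1L, 1L, 1L,
    2L, 2L, 2L,
    4L, 3L, 3L,
    3L, 4L, 4L),
  nrow = 4, byrow = TRUE,
  dimnames = list(NULL, c("color", "shape", "number"))
)

.as_target <- function(target) {
  if (is.data.frame(target)) {
    stopifnot(nrow(target) == 1)
    target <- c(target$color, target$shape, target$number)
  }
  target <- as.integer(target)
  if (length(target) != 3 || anyNA(target) || any(target < 1L | target > 4L)) {
    rlang::abort("`target` must be three feature values (color, shape, number) in 1..4.")
  }
  target
}

#' Feature-match vector between a target card and a chosen stimulus card
#'
#' Component i is 1 iff the chosen stimulus card equals the target on feature
#' dimension i (1 = color, 2 = shape, 3 = number). Because the stimulus cards
#' are pairwise distinct on every dimension, each component is 1 for exactly
#' one of the four possible actions.
#'
#' @param target Target card: an integer vector `c(color, shape, number)`
#'   with values in 1..4, or a one-row data frame with those columns.
#' @param action Chosen stimulus card index in 1..4.
#' @return Integer vector of length 3.
#' @examples
#' match_vector(c(3, 2, 3), 2)  # blue star with 3 objects vs. two green stars
#' @export
match_vector <- function(target, action) {
  target <- .as_target(target)
  action <- as.integer(action)
  if (length(action) != 1 || is.na(action) || action < 1L || action > 4L) {
    rlang::abort("`action` must be a single card index in 1..4.")
  }
  as.integer(.deck_matrix[action, ] == target)
}

#' Stimulus card matching a target on a given feature dimension
#'
#' Inverse of [match_vector()]: returns the unique card index whose feature
#' `feature` equals the target's.
#'
#' @inheritParams match_vector
#' @param feature Feature dimension: 1 (color), 2 (shape) or 3 (number), or
#'   one of `"color"`, `"shape"`, `"number"`.
#' @return Card index in 1..4.
#' @examples
#' card_for_feature(c(3, 2, 3), "color")
#' @export
card_for_feature <- function(target, feature) {
  target <- .as_target(target)
  feature <- .as_feature(feature)
  which(.deck_matrix[, feature] == target[feature])
}

.as_feature <- function(feature) {
  if (is.character(feature)) {
    feature <- match(feature, .wcst_features)
  }
  feature <- as.integer(feature)
  if (length(feature) != 1 || is.na(feature) || feature < 1L || feature > 3L) {
    rlang::abort("`feature` must be 1..3 or one of \"color\", \"shape\", \"number\".")
  }
  feature
}

#' Examiner feedback for a response
#'
#' Feedback is 1 iff the chosen card matches the target on the currently
#' valid sorting rule, else 0.
#'
#' @inheritParams match_vector
#' @param rule Current true sorting rule (feature index 1..3 or name).
#' @return 0 or 1.
#' @export
give_feedback <- function(target, action, rule) {
  match_vector(target, action)[.as_feature(rule)]
}

#' Draw target cards
#'
#' Draws target cards for a simulated session. Under `"uniform60"` (default)
#' targets are drawn uniformly from the 60 feature combinations that are not
#' identical to a stimulus card (a target equal to a stimulus card would match
#' it on all three dimensions and make the trial uninformative). Under
#' `"uniform64"` all 64 combinations are allowed. Under `"fixed"` the supplied
#' `cards` are used in order.
#'
#' Uses the current RNG state; seed at the caller for reproducibility.
#'
#' @param n Number of targets to draw.
#' @param policy One of `"uniform60"`, `"uniform64"`, `"fixed"`.
#' @param cards For `policy = "fixed"`: a data frame with columns `color`,
#'   `shape`, `number` and at least `n` rows.
#' @return A tibble with columns `color`, `shape`, `number` (`n` rows).
#' @export
draw_targets <- function(n, policy = c("uniform60", "uniform64", "fixed"),
                         cards = NULL) {
  policy <- match.arg(policy)
  n <- as.integer(n)
  if (policy == "fixed") {
    if (is.null(cards)) rlang::abort("`cards` must be supplied for the fixed-list policy.")
    if (nrow(cards) < n) {
      rlang::abort(sprintf(
        "fixed-list target deck exhausted: %d cards supplied, %d trials requested.",
        nrow(cards), n))
    }
    return(tibble::as_tibble(cards[seq_len(n), c("color", "shape", "number")]))
  }
  pool <- .target_pool(policy)
  idx <- sample.int(nrow(pool), n, replace = TRUE)
  tibble::as_tibble(as.data.frame(pool[idx, , drop = FALSE]))
}

.target_pool <- function(policy) {
  all64 <- as.matrix(expand.grid(color = 1:4, shape = 1:4, number = 1:4,
                                 KEEP.OUT.ATTRS = FALSE))
  storage.mode(all64) <- "integer"
  if (policy == "uniform64") return(all64)
  is_stim <- apply(all64, 1, function(x) any(colSums(t(.deck_matrix) == x) == 3))
  all64[!is_stim, , drop = FALSE]
}

#' Task configuration for a WCST session
#'
#' @param n_trials Maximum number of trials (default 128, the Heaton two-deck
#'   protocol length).
#' @param consecutive_to_complete Consecutive correct responses completing a
#'   category and triggering an unannounced rule change (default 10).
#' @param max_categories Session also ends after this many completed
#'   categories (default `Inf`; the clinical application protocol uses 6).
#' @param rule_sequence Cyclic order of sorting rules, default color, shape,
#'   number.
#' @param deck_policy Target-draw policy, see [draw_targets()].
#' @param targets Optional fixed target list (data frame with `color`,
#'   `shape`, `number`) used when `deck_policy = "fixed"`.
#' @return A list of class `"wcst_config"`.
#' @export
task_config <- function(n_trials = 128L,
                        consecutive_to_complete = 10L,
                        max_categories = Inf,
                        rule_sequence = c("color", "shape", "number"),
                        deck_policy = c("uniform60", "uniform64", "fixed"),
                        targets = NULL) {
  deck_policy <- match.arg(deck_policy)
  n_trials <- as.integer(n_trials)
  consecutive_to_complete <- as.integer(consecutive_to_complete)
  if (n_trials < 1L) rlang::abort("`n_trials` must be at least 1.")
  if (consecutive_to_complete < 1L) rlang::abort("`consecutive_to_complete` must be at least 1.")
  rule_sequence <- vapply(rule_sequence, .as_feature, integer(1), USE.NAMES = FALSE)
  if (!is.null(targets)) deck_policy <- "fixed"
  structure(
    list(n_trials = n_trials,
         consecutive_to_complete = consecutive_to_complete,
         max_categories = max_categories,
         rule_sequence = rule_sequence,
         deck_policy = deck_policy,
         targets = targets),
    class = "wcst_config")
}

#' @export
print.wcst_config <- function(x, ...) {
  cat("<wcst_config>\n")
  cat("  trials:", x$n_trials,
      " consecutive to complete:", x$consecutive_to_complete,
      " max categories:", x$max_categories, "\n")
  cat("  rule sequence:", paste(.wcst_features[x$rule_sequence], collapse = " -> "),
      "(cyclic)\n")
  cat("  target deck:", x$deck_policy, "\n")
  invisible(x)
}
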
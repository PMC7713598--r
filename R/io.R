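#' Read and write WCST session logs
#'
#' Session logs are comma-separated text with a header row and one row per
#' trial, columns `trial`, `target_color`, `target_shape`, `target_number`,
#' `action`, `feedback` and optionally `true_rule` (empty for observed human
#' data). Writing then reading a session reproduces these columns exactly.
#'
#' @param session A `wcst_session` or compatible data frame.
#' @param path File path.
#' @return `read_session()` returns a `wcst_session` tibble;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  cols <- c("trial", "target_color", "target_shape", "target_number",
            "action", "feedback")
  if ("true_rule" %in% names(session)) cols <- c(cols, "true_rule")
  readr::write_csv(tibble::as_tibble(session)[cols], path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such session file: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) rlang::abort("Empty session file.")
  validate_session(x)
  x <- ensure_match_columns(tibble::as_tibble(x))
  new_wcst_session(x)
}

#' Validate a session table
#'
#' Checks required columns, feature ranges (1..4), action range (1..4),
#' binary feedback, consecutive 1-based trial indices, and (when present)
#' rule range (1..3). Aborts with the offending rows named.
#'
#' @param x A data frame.
#' @return `x`, invisibly, if valid.
#' @export
validate_session <- function(x) {
  required <- c("trial", "target_color", "target_shape", "target_number",
                "action", "feedback")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    rlang::abort(paste0("Session is missing required columns: ",
                        paste(missing, collapse = ", ")))
  }
  bad_rows <- function(cond) which(cond | is.na(cond))
  checks <- list(
    "feature values outside 1..4" = bad_rows(
      x$target_color < 1 | x$target_color > 4 |
      x$target_shape < 1 | x$target_shape > 4 |
      x$target_number < 1 | x$target_number > 4),
    "action outside 1..4" = bad_rows(x$action < 1 | x$action > 4),
    "feedback outside {0, 1}" = bad_rows(!x$feedback %in% c(0, 1)))
  if ("true_rule" %in% names(x) && !all(is.na(x$true_rule))) {
    checks[["true_rule outside 1..3"]] <-
      which(!is.na(x$true_rule) & (x$true_rule < 1 | x$true_rule > 3))
  }
  for (what in names(checks)) {
    rows <- checks[[what]]
    if (length(rows)) {
      rlang::abort(sprintf("Invalid session: %s in row(s) %s.", what,
                           paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  if (!identical(as.integer(x$trial), seq_len(nrow(x)))) {
    rlang::abort("Invalid session: `trial` must run 1, 2, ... without gaps.")
  }
  invisible(x)
}

#' Export a posterior summary as JSON
#'
#' @param posterior A `wcst_posterior`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(posterior, path) {
  jsonlite::write_json(
    list(n_trials = posterior$n_trials,
         log_evidence = posterior$log_evidence,
         parameters = posterior$summary),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
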
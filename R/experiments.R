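#' Factorial simulation of agent cohorts
#'
#' Simulates `n_agents` sessions per cell of a flexibility-by-information-loss
#' factorial design and scores each session with the clinical scorer. The
#' default design is the clinical-assessment simulation: lambda in
#' {0.3, 0.5, 0.7, 0.9}, delta in {0.4, 0.7, 0.9}, 150 agents per cell on
#' the 128-trial protocol.
#'
#' A master seed spawns per-agent substreams, so cohorts are reproducible
#' and cells are independent.
#'
#' @param lambda_levels,delta_levels Parameter levels of the design.
#' @param n_agents Agents per cell.
#' @param config Session protocol.
#' @param seed Master seed.
#' @param pe_rule Perseveration criterion, see [classify_errors()].
#' @param params_template Semantics/floor template for the generator.
#' @return A tibble with one row per agent: `lambda`, `delta`, `agent`,
#'   `seed` and the [score_session()] columns.
#' @examples
#' \donttest{
#' scores <- run_factorial(n_agents = 20, seed = 1)
#' summarize_factorial(scores)
#' }
#' @export
run_factorial <- function(lambda_levels = c(0.3, 0.5, 0.7, 0.9),
                          delta_levels = c(0.4, 0.7, 0.9),
                          n_agents = 150L,
                          config = task_config(),
                          seed = 1L,
                          pe_rule = c("principle", "unambiguous", "sandwich"),
                          params_template = NULL) {
  pe_rule <- match.arg(pe_rule)
  if (is.null(params_template)) params_template <- agent_params(0.5, 0.5)
  design <- tidyr::expand_grid(lambda = lambda_levels, delta = delta_levels)
  n_cells <- nrow(design)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_cells * n_agents),
           nrow = n_cells))

  purrr::pmap(
    list(design$lambda, design$delta, seq_len(n_cells)),
    function(lam, del, cell) {
      params <- agent_params(lam, del,
                             lapse = params_template$lapse,
                             activation_floor = params_template$activation_floor,
                             semantics = params_template$semantics,
                             matching_signal = params_template$matching_signal)
      purrr::map(seq_len(n_agents), function(i) {
        s <- run_agent(params, config, seed = seeds[cell, i])
        dplyr::mutate(score_session(s, pe_rule),
                      lambda = lam, delta = del, agent = i,
                      seed = seeds[cell, i], .before = 1)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
}

#' Per-cell summary of a factorial cohort
#'
#' Long-format means and across-agent standard deviations of the four
#' clinical measures per design cell, the conventional factorial-table
#' layout.
#'
#' @param scores Output of [run_factorial()].
#' @return A tibble with columns `lambda`, `delta`, `measure`, `mean`, `sd`.
#' @export
summarize_factorial <- function(scores) {
  scores |>
    dplyr::select("lambda", "delta",
                  E = "other_errors", PE = "perseverative_errors",
                  TFC = "trials_to_first_category",
                  FMS = "failures_to_maintain_set") |>
    tidyr::pivot_longer(c("E", "PE", "TFC", "FMS"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$lambda, .data$delta, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
                     .groups = "drop")
}

#' Information-theoretic dynamics across a parameter grid
#'
#' Simulates one session per cell of a small parameter grid (default: the
#' information-theoretic exploration grid lambda, delta in {0.1, 0.5, 0.9})
#' and reconstructs the trial-by-trial Bayesian surprise, Shannon surprise
#' and predictive entropy series.
#'
#' @param lambda_levels,delta_levels Grid levels.
#' @param config Session protocol.
#' @param seed Master seed.
#' @param n_sessions Sessions per cell (default 1).
#' @return A tibble with columns `lambda`, `delta`, `session`, `trial`,
#'   `bayesian_surprise`, `shannon_surprise`, `entropy`.
#' @export
run_info_dynamics <- function(lambda_levels = c(0.1, 0.5, 0.9),
                              delta_levels = c(0.1, 0.5, 0.9),
                              config = task_config(),
                              seed = 1L,
                              n_sessions = 1L) {
  design <- tidyr::expand_grid(lambda = lambda_levels, delta = delta_levels)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nrow(design) * n_sessions),
           nrow = nrow(design)))
  purrr::pmap(
    list(design$lambda, design$delta, seq_len(nrow(design))),
    function(lam, del, cell) {
      purrr::map(seq_len(n_sessions), function(k) {
        s <- run_agent(agent_params(lam, del), config, seed = seeds[cell, k])
        traj <- reconstruct_trajectories(s)
        dplyr::mutate(tibble::as_tibble(traj),
                      lambda = lam, delta = del, session = k, .before = 1)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
}

#' Synthetic cohort with group structure
#'
#' Draws per-individual parameters from truncated-normal group distributions
#' on the unit interval, simulates one session per individual, and returns
#' sessions together with the ground truth — the fixture generator for
#' end-to-end recovery and group-separation checks.
#'
#' @param groups A data frame with one row per group and columns `group`,
#'   `n`, `lambda_mean`, `lambda_sd`, `delta_mean`, `delta_sd`.
#' @param config Session protocol.
#' @param seed Master seed.
#' @return A list with `truth` (tibble: `group`, `id`, `lambda`, `delta`,
#'   `seed`) and `sessions` (list of `wcst_session`, aligned with `truth`).
#' @export
synthetic_cohort <- function(groups, config = task_config(), seed = 1L) {
  stopifnot(all(c("group", "n", "lambda_mean", "lambda_sd",
                  "delta_mean", "delta_sd") %in% names(groups)))
  truth <- withr::with_seed(seed, {
    purrr::pmap(groups, function(group, n, lambda_mean, lambda_sd,
                                 delta_mean, delta_sd, ...) {
      if (n == 0) return(NULL)
      tibble::tibble(
        group = group,
        id = seq_len(n),
        lambda = .rtrunc01(n, lambda_mean, lambda_sd),
        delta = .rtrunc01(n, delta_mean, delta_sd),
        seed = sample.int(.Machine$integer.max - 1L, n))
    }) |> purrr::list_rbind()
  })
  sessions <- purrr::pmap(
    truth[c("lambda", "delta", "seed")],
    function(lambda, delta, seed) {
      run_agent(agent_params(lambda, delta), config, seed = seed)
    })
  list(truth = truth, sessions = sessions)
}

# truncated-normal on [0, 1] by resampling (falls back to clamping for
# extreme tail placements)
.rtrunc01 <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- out < 0 | out > 1
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, 0), 1)
}
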
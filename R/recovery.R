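#' Simulation-based validation of parameter recovery
#'
#' Draws `n_sets` parameter pairs from the uniform prior on the unit square,
#' simulates one session each, computes the gridded posterior, and summarises
#' recovery quality with the validation metrics: per-parameter RMSE and
#' R-squared of posterior means against ground truth, calibration error
#' (mean absolute difference between nominal and empirical coverage of
#' central credible intervals across an alpha grid), and simulation-based
#' calibration (SBC) ranks of the true values among posterior draws.
#'
#' @param n_sets Number of validation sessions (>= 100 recommended).
#' @param config Session protocol (default 128 trials).
#' @param grid Posterior [param_grid()].
#' @param seed Master seed; per-set substreams are derived from it.
#' @param alphas Nominal central-coverage levels for the calibration error.
#' @param sbc_draws Posterior draws per data set for SBC ranks (ranks run
#'   from 0 to `sbc_draws`).
#' @param params_template Semantics/floor template for generator and
#'   likelihood (defaults to package defaults with `lapse = 0`).
#' @return An object of class `"wcst_recovery"`: list with `results`
#'   (per-set tibble: truths, posterior means, credible bounds per alpha,
#'   SBC ranks), `metrics` (per-parameter rmse, r_squared,
#'   calibration_error), `coverage` (per parameter and alpha), and the study
#'   settings.
#' @examples
#' \donttest{
#' rec <- recovery_study(n_sets = 20, grid = param_grid(41, 41), seed = 1)
#' tidy(rec)
#' }
#' @export
recovery_study <- function(n_sets = 300L,
                           config = task_config(),
                           grid = param_grid(),
                           seed = NULL,
                           alphas = seq(0.05, 0.95, by = 0.05),
                           sbc_draws = 99L,
                           params_template = NULL) {
  n_sets <- as.integer(n_sets)
  if (is.null(params_template)) params_template <- agent_params(0.5, 0.5)
  run <- function() {
    truths <- tibble::tibble(lambda = stats::runif(n_sets),
                             delta = stats::runif(n_sets),
                             seed = sample.int(.Machine$integer.max - 1L, n_sets))
    results <- purrr::pmap(truths, function(lambda, delta, seed) {
      params <- agent_params(lambda, delta,
                             lapse = params_template$lapse,
                             activation_floor = params_template$activation_floor,
                             semantics = params_template$semantics,
                             matching_signal = params_template$matching_signal)
      session <- run_agent(params, config, seed = seed)
      post <- grid_posterior(session, grid, lapse = params_template$lapse,
                             params_template = params_template)
      .recovery_row(post, lambda, delta, alphas, sbc_draws)
    }) |> purrr::list_rbind()
    list(truths = truths, results = results)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  truths <- out$truths
  results <- out$results
  results$set <- seq_len(n_sets)
  results$lambda_true <- truths$lambda
  results$delta_true <- truths$delta

  metrics <- purrr::map(c("lambda", "delta"), function(par) {
    truth <- results[[paste0(par, "_true")]]
    est <- results[[paste0(par, "_mean")]]
    cov_par <- purrr::map_dbl(alphas, function(a) {
      mean(results[[sprintf("%s_cover_%02d", par, round(100 * a))]])
    })
    tibble::tibble(
      parameter = par,
      rmse = sqrt(mean((est - truth)^2)),
      r_squared = 1 - sum((truth - est)^2) / sum((truth - mean(truth))^2),
      calibration_error = mean(abs(cov_par - alphas)))
  }) |> purrr::list_rbind()

  coverage <- tidyr::expand_grid(parameter = c("lambda", "delta"), alpha = alphas) |>
    dplyr::mutate(coverage = purrr::map2_dbl(.data$parameter, .data$alpha, function(p, a) {
      mean(results[[sprintf("%s_cover_%02d", p, round(100 * a))]])
    }))

  structure(
    list(results = results, metrics = metrics, coverage = coverage,
         n_sets = n_sets, sbc_draws = sbc_draws, alphas = alphas, seed = seed),
    class = "wcst_recovery")
}

.recovery_row <- function(post, lambda_true, delta_true, alphas, sbc_draws) {
  est <- setNames(post$summary$mean, post$summary$parameter)
  draws <- posterior_draws(post, sbc_draws)
  row <- tibble::tibble(
    lambda_mean = est[["lambda"]],
    delta_mean = est[["delta"]],
    lambda_rank = sum(draws$lambda < lambda_true),
    delta_rank = sum(draws$delta < delta_true))
  for (par in c("lambda", "delta")) {
    m <- .marginal(post$grid, par)
    truth <- if (par == "lambda") lambda_true else delta_true
    for (a in alphas) {
      q <- .weighted_quantile(m$value, m$mass, c((1 - a) / 2, (1 + a) / 2))
      row[[sprintf("%s_cover_%02d", par, round(100 * a))]] <-
        truth >= q[1] && truth <= q[2]
    }
  }
  row
}

#' @export
print.wcst_recovery <- function(x, ...) {
  cat(sprintf("<wcst_recovery> %d validation sets, %d SBC draws/set\n",
              x$n_sets, x$sbc_draws))
  print(x$metrics)
  invisible(x)
}

#' @rdname recovery_study
#' @param x A `wcst_recovery`.
#' @param ... Unused.
#' @method tidy wcst_recovery
#' @export
tidy.wcst_recovery <- function(x, ...) {
  x$metrics
}

#' @rdname recovery_study
#' @method glance wcst_recovery
#' @export
glance.wcst_recovery <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_sets = x$n_sets,
    rmse_lambda = m$rmse[m$parameter == "lambda"],
    rmse_delta = m$rmse[m$parameter == "delta"],
    r_squared_lambda = m$r_squared[m$parameter == "lambda"],
    r_squared_delta = m$r_squared[m$parameter == "delta"],
    calibration_error_lambda = m$calibration_error[m$parameter == "lambda"],
    calibration_error_delta = m$calibration_error[m$parameter == "delta"])
}

#' Chi-square uniformity test of SBC ranks
#'
#' Bins the SBC ranks (0..`sbc_draws`) of a recovery study into `bins`
#' equally sized bins and tests uniformity with a chi-square
#' goodness-of-fit test. Systematic deviations indicate biased posteriors.
#'
#' @param recovery A `wcst_recovery`.
#' @param parameter `"lambda"` or `"delta"`.
#' @param bins Number of histogram bins (default 20).
#' @return The `htest` object from [stats::chisq.test()].
#' @export
sbc_uniformity_test <- function(recovery, parameter = c("lambda", "delta"),
                                bins = 20L) {
  parameter <- match.arg(parameter)
  ranks <- recovery$results[[paste0(parameter, "_rank")]]
  n_levels <- recovery$sbc_draws + 1L
  bin <- pmin(floor(ranks / (n_levels / bins)), bins - 1L)
  counts <- tabulate(bin + 1L, nbins = bins)
  stats::chisq.test(counts)
}
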
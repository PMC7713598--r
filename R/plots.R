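#' Plot information-theoretic trajectories
#'
#' Line panels of Bayesian surprise, Shannon surprise and predictive entropy
#' across trials.
#'
#' @param object A `wcst_trajectory` from [reconstruct_trajectories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wcst_trajectory
#' @export
autoplot.wcst_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("bayesian_surprise", "shannon_surprise", "entropy"),
    names_to = "measure", values_to = "nats")
  long$measure <- factor(long$measure,
                         levels = c("bayesian_surprise", "shannon_surprise", "entropy"),
                         labels = c("Bayesian surprise", "Shannon surprise",
                                    "Predictive entropy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$nats)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = "nats") +
    ggplot2::theme_minimal()
}

#' Plot a gridded parameter posterior
#'
#' Raster of the joint posterior over flexibility and information loss, with
#' the posterior mean marked.
#'
#' @param object A `wcst_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wcst_posterior
#' @export
autoplot.wcst_posterior <- function(object, ...) {
  est <- setNames(object$summary$mean, object$summary$parameter)
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$lambda, y = .data$delta,
                               fill = .data$posterior)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = tibble::tibble(lambda = est[["lambda"]], delta = est[["delta"]]),
      ggplot2::aes(x = .data$lambda, y = .data$delta),
      inherit.aes = FALSE, colour = "white", shape = 3, size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(lambda ~ "(flexibility)"),
                  y = expression(delta ~ "(information loss)"),
                  fill = "mass") +
    ggplot2::theme_minimal()
}

#' Plot recovery diagnostics
#'
#' Scatter of posterior means against ground truth per parameter, with the
#' identity line.
#'
#' @param object A `wcst_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wcst_recovery
#' @export
autoplot.wcst_recovery <- function(object, ...) {
  res <- object$results
  long <- dplyr::bind_rows(
    tibble::tibble(parameter = "lambda", truth = res$lambda_true,
                   estimate = res$lambda_mean),
    tibble::tibble(parameter = "delta", truth = res$delta_true,
                   estimate = res$delta_mean))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter)) +
    ggplot2::labs(x = "ground truth", y = "posterior mean") +
    ggplot2::theme_minimal()
}

#' SBC rank histogram
#'
#' @param recovery A `wcst_recovery`.
#' @param parameter `"lambda"` or `"delta"`.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_sbc <- function(recovery, parameter = c("lambda", "delta"), bins = 20L) {
  parameter <- match.arg(parameter)
  ranks <- recovery$results[[paste0(parameter, "_rank")]]
  n_levels <- recovery$sbc_draws + 1L
  expected <- length(ranks) / bins
  df <- tibble::tibble(bin = pmin(floor(ranks / (n_levels / bins)), bins - 1L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::geom_hline(yintercept = expected, linetype = 2) +
    ggplot2::labs(x = sprintf("SBC rank bin (%s)", parameter), y = "count") +
    ggplot2::theme_minimal()
}

#' Violin plots of clinical scores across a factorial design
#'
#' @param scores Output of [run_factorial()].
#' @return A ggplot object faceted by measure and information loss.
#' @export
plot_factorial <- function(scores) {
  long <- scores |>
    dplyr::select("lambda", "delta",
                  E = "other_errors", PE = "perseverative_errors",
                  TFC = "trials_to_first_category",
                  FMS = "failures_to_maintain_set") |>
    tidyr::pivot_longer(c("E", "PE", "TFC", "FMS"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$lambda), y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::facet_grid(ggplot2::vars(.data$measure), ggplot2::vars(.data$delta),
                        scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(lambda), y = NULL) +
    ggplot2::theme_minimal()
}
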
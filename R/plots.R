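#' Stay-probability bar chart
#'
#' Group means (with standard-error bars) of the per-subject stay
#' probabilities by previous outcome and previous transition, one panel per
#' condition — the standard visual diagnostic separating model-free
#' (outcome main effect) from model-based (outcome-by-transition crossover)
#' behavior.
#'
#' @param stays A stay table from [stay_probabilities()].
#' @return A ggplot object.
#' @export
plot_stay_probabilities <- function(stays) {
  has_cond <- "condition" %in% names(stays)
  summ <- stays |>
    dplyr::filter(is.finite(.data$stay_prob)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(if (has_cond) "condition", "prev_outcome", "prev_transition")))) |>
    dplyr::summarise(
      mean_stay = mean(.data$stay_prob),
      sem = stats::sd(.data$stay_prob) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$prev_outcome, y = .data$mean_stay, fill = .data$prev_transition
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_stay - .data$sem,
                   ymax = .data$mean_stay + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "previous outcome", y = "stay probability",
                  fill = "previous transition") +
    ggplot2::theme_minimal()
  if (has_cond) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' Fitted-parameter group means
#'
#' Means and standard errors of each fitted parameter by condition.
#'
#' @param fits A fitted-parameter tibble from [fit_cohort()].
#' @return A ggplot object.
#' @export
plot_parameter_estimates <- function(fits) {
  long <- fits |>
    tidyr::pivot_longer(dplyr::all_of(param_names),
                        names_to = "term", values_to = "estimate") |>
    dplyr::group_by(.data$condition, .data$term) |>
    dplyr::summarise(mean = mean(.data$estimate),
                     sem = stats::sd(.data$estimate) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(term = factor(.data$term, levels = param_names))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "parameter estimate", fill = NULL) +
    ggplot2::theme_minimal()
}

#' True-versus-recovered parameter scatter
#'
#' One panel per parameter, true value against maximum-likelihood recovery,
#' with the identity line.
#'
#' @param truth Ground-truth tibble (as from [cohort_truth()]).
#' @param fits Fitted-parameter tibble (as from [fit_cohort()]).
#' @return A ggplot object.
#' @export
plot_parameter_recovery <- function(truth, fits) {
  joined <- dplyr::inner_join(
    truth |>
      tidyr::pivot_longer(dplyr::all_of(param_names),
                          names_to = "term", values_to = "true"),
    fits |>
      tidyr::pivot_longer(dplyr::all_of(param_names),
                          names_to = "term", values_to = "fitted") |>
      dplyr::select("subject_id", "term", "fitted"),
    by = c("subject_id", "term")
  )
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$true, y = .data$fitted)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "true parameter", y = "recovered parameter",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
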
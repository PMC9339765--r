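#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-surveyor detection probabilities
#'
#' Point estimates with 95% intervals for each surveyor (Mt fit) or
#' experience group, coloured by experience.
#'
#' @param object A `huggins_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.huggins_fit <- function(object, ...) {
  pr <- detection_probs(object)
  pr$surveyor_id <- factor(pr$surveyor_id, levels = pr$surveyor_id)
  ggplot2::ggplot(
    pr,
    ggplot2::aes(
      x = .data$surveyor_id, y = .data$estimate,
      colour = .data$experience
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lcl, ymax = .data$ucl)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Detection probability", colour = "Experience"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the permutation distribution of removal estimates
#'
#' Histogram of the finite depletion-regression x-intercepts across
#' permutations, per plot, with the median and 95% percentile interval.
#'
#' @param object A `removal_estimate`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.removal_estimate <- function(object, bins = 40, ...) {
  draws <- attr(object, "draws")
  df <- purrr::imap(
    draws, \(v, p) tibble::tibble(plot_id = p, estimate = v)
  ) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(
      data = tibble::as_tibble(object),
      ggplot2::aes(xintercept = .data$estimate), colour = "blue"
    ) +
    ggplot2::geom_vline(
      data = tidyr::pivot_longer(
        tibble::as_tibble(object)[c("plot_id", "lcl", "ucl")],
        c("lcl", "ucl")
      ),
      ggplot2::aes(xintercept = .data$value), linetype = 2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$plot_id), scales = "free") +
    ggplot2::labs(x = "Estimated population size", y = "Permutations") +
    ggplot2::theme_minimal()
}

#' Plot accuracy or precision against surveyor number
#'
#' Jittered per-subset values with the mean and a 1.96-standard-error
#' band per k, for the relative error or the relative CI width of a
#' reduced-effort scan.
#'
#' @param object An `effort_scan`.
#' @param metric `"rel_error"` or `"rel_ci_width"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.effort_scan <- function(object,
                                 metric = c("rel_error",
                                            "rel_ci_width"),
                                 ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(
    tibble::as_tibble(object), .data$reliable,
    is.finite(.data[[metric]])
  )
  mm <- df |>
    dplyr::summarise(
      m = mean(.data[[metric]]),
      se = stats::sd(.data[[metric]]) / sqrt(dplyr::n()),
      .by = "k"
    )
  lab <- if (metric == "rel_error") "Relative error" else
    "Relative 95% CI width"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.12, height = 0, colour = "grey60",
                         size = 1) +
    ggplot2::geom_pointrange(
      data = mm,
      ggplot2::aes(y = .data$m, ymin = .data$m - 1.96 * .data$se,
                   ymax = .data$m + 1.96 * .data$se),
      colour = "blue"
    ) +
    ggplot2::labs(x = "Number of surveyors", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot observed vs simulated detection-count frequencies
#'
#' Bars show the simulated median frequency of individuals detected k
#' times under equal detectability, with 95% envelopes; dots show the
#' observed frequencies.
#'
#' @param object A `detectability_check`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detectability_check <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$sim_median),
                      fill = "grey75") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$sim_lcl, ymax = .data$sim_ucl),
      width = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "blue", size = 2) +
    ggplot2::labs(x = "Times detected", y = "Number of individuals") +
    ggplot2::theme_minimal()
}
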
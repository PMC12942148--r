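#' Plot per-cell classification accuracy of an experiment
#'
#' Mean recall, precision and F1 per method against test length, faceted by
#' prevalence and severity — the standard at-a-glance view of a simulation
#' sweep.
#'
#' @param results Tibble from [run_experiment()].
#' @param metric One or more of `"recall"`, `"precision"`, `"f1"`.
#' @return A ggplot object.
#' @export
plot_experiment <- function(results, metric = c("recall", "precision", "f1")) {
  metric <- match.arg(metric, several.ok = TRUE)
  summ <- summarize_experiment(results) |>
    tidyr::pivot_longer(dplyr::all_of(metric),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$J), y = .data$value,
                                     colour = .data$method,
                                     group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$pi, .data$severity),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "test length J", y = NULL, colour = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Histogram of lz* with the flagging threshold
#'
#' @param pf Tibble from [person_fit()] (columns `lz_star`, `flagged`).
#' @param critical Threshold to draw.
#' @return A ggplot object.
#' @export
plot_person_fit <- function(pf, critical = -1.645) {
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$lz_star, fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30") +
    ggplot2::geom_vline(xintercept = critical, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               na.value = "grey90") +
    ggplot2::labs(x = "lz*", y = "persons", fill = "flagged") +
    ggplot2::theme_bw()
}

#' Accuracy vs. time scatter of a simulated or classified sample
#'
#' The usual diagnostic view: proportion correct against log mean response
#' time, colored by effort label. Rapid guessers sit fast-and-near-chance,
#' effortful respondents slow-and-accurate.
#'
#' @param sim An `effort_sim`.
#' @param effortful Optional predicted labels; defaults to the truth.
#' @return A ggplot object.
#' @export
plot_effort_scatter <- function(sim, effortful = NULL) {
  d <- tidy(sim)
  d$label <- if (is.null(effortful)) !d$is_noneffortful else effortful
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$mean_rt),
                                  y = .data$prop_correct,
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log mean response time (s)", y = "proportion correct",
                  colour = "effortful") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_effort_scatter
#' @param object An `effort_sim`.
#' @param ... Unused.
#' @method autoplot effort_sim
#' @export
autoplot.effort_sim <- function(object, ...) plot_effort_scatter(object)

#' @rdname run_two_step
#' @param object A `two_step` object (for `autoplot`).
#' @method autoplot two_step
#' @export
autoplot.two_step <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lz_star, fill = .data$effortful)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$critical, linetype = 2) +
    ggplot2::labs(x = "lz* (evaluated persons)", y = "persons",
                  fill = "final effortful") +
    ggplot2::theme_bw()
}
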
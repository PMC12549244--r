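# Figures: per-participant trust traces and predicted-vs-reported scatter.

#' Plot predicted and reported trust traces per participant
#'
#' One panel per participant: reported trust and the model's capped
#' predictions across the report split's withheld epochs, in session/trial
#' order, with dashed delimiters between sessions.  Mirrors the standard
#' temporal-fluctuation visualization for trust models.
#'
#' @param mccv A [run_mccv()] result (with stored predictions).
#' @return A ggplot object.
#' @export
plot_trust_traces <- function(mccv) {
  stopifnot(inherits(mccv, "trust_mccv"))
  assert_that(!is.null(mccv$predictions),
              "mccv carries no stored predictions (report_split not run)")
  df <- mccv$predictions |>
    arrange(.data$participant, .data$session, .data$trial, .data$epoch) |>
    group_by(.data$participant) |>
    mutate(t = dplyr::row_number()) |>
    ungroup()
  delim <- df |>
    group_by(.data$participant, .data$session) |>
    summarise(t = max(.data$t) + 0.5, .groups = "drop") |>
    group_by(.data$participant) |>
    filter(.data$t < max(.data$t)) |>
    ungroup()
  long <- df |>
    select("participant", "t", reported = "y", predicted = ".pred") |>
    pivot_longer(c("reported", "predicted"),
                 names_to = "series", values_to = "trust")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$trust,
                                     color = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(data = delim, ggplot2::aes(xintercept = .data$t),
                        linetype = "dashed", color = "grey60") +
    ggplot2::facet_wrap(~participant, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::scale_color_manual(values = c(reported = "firebrick",
                                           predicted = "navy")) +
    ggplot2::labs(x = "withheld epoch (session/trial order)",
                  y = "trust", color = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_mccv Predicted vs reported trust for the report split,
#'   with the unity line.
#' @param object A `trust_mccv`.
#' @export
autoplot.trust_mccv <- function(object, ...) {
  assert_that(!is.null(object$predictions),
              "mccv carries no stored predictions")
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$y, .data$.pred,
                               color = factor(.data$participant))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "reported trust", y = "predicted trust",
                  color = "participant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
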
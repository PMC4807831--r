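#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-activity curve
#'
#' @param object A `tac` tibble.
#' @param log_y Log-scale the activity axis (default `TRUE`; exponential
#'   decays plot as straight lines).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.tac <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_mid, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time since injection (s)",
      y = if (is_decay_corrected(object)) {
        "ROI activity, decay-corrected (Bq)"
      } else {
        "ROI activity (Bq)"
      }
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the fitted exponential over its TAC
#'
#' @param object A `washout_fit`.
#' @param log_y Log-scale the activity axis.
#' @param ... Unused.
#'
#' @return A ggplot object with the frame data and the fitted
#'   frame-averaged model curve.
#' @export
autoplot.washout_fit <- function(object, log_y = TRUE, ...) {
  d <- object$data
  d$fitted <- object$amplitude *
    frame_mean_exp(object$lambda, d$t_start, d$duration)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "time since injection (s)", y = "ROI activity (Bq)",
      subtitle = sprintf("T1/2 = %.0f s", object$halflife)
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot all TACs of a study, faceted by condition
#'
#' @param study Study tibble with a `tac` list-column.
#' @param log_y Log-scale the activity axis.
#'
#' @return A ggplot object, one line per animal, alive and dead panels.
#' @export
plot_study_tacs <- function(study, log_y = TRUE) {
  stopifnot(is.data.frame(study), "tac" %in% names(study))
  d <- study |>
    dplyr::mutate(tac = purrr::map(.data$tac, tibble::as_tibble)) |>
    dplyr::select("animal_id", "condition", "tac") |>
    tidyr::unnest("tac")
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$t_mid, y = .data$value,
                    colour = factor(.data$animal_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time since injection (s)",
                  y = "ROI activity, decay-corrected (Bq)",
                  colour = "animal")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot group summaries as mean +/- SD half-lives
#'
#' @param summaries Tibble from [summarize_group()] rows (columns
#'   `tissue`, `component`, `mean_halflife`, `sd_halflife`).
#'
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summaries) {
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$tissue, y = .data$mean_halflife,
                 fill = .data$component)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_halflife - .data$sd_halflife,
                   ymax = .data$mean_halflife + .data$sd_halflife),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "half-life (s)", fill = NULL)
}
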
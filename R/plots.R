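#' Plot a subpopulation or marker positivity trajectory
#'
#' Bars (or lines, with `geom = "line"`) of the positive fraction per
#' timepoint, as produced by [subpopulation_trajectory()] or
#' [positive_fraction_by_timepoint()].
#'
#' @param traj Trajectory tibble with `timepoint` and `fraction`.
#' @param geom `"col"` or `"line"`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, geom = c("col", "line")) {
  geom <- match.arg(geom)
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$timepoint,
                                          y = .data$fraction))
  p <- if (geom == "col") {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_line(ggplot2::aes(group = 1)) + ggplot2::geom_point()
  }
  p + ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "positive fraction") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for dichotomized groups
#'
#' @param times,events Survival data.
#' @param group Group labels (e.g. the `group` element of a
#'   [find_cutpoint()] result).
#' @return A ggplot step-curve object.
#' @export
plot_km <- function(times, events, group) {
  g <- as.factor(group)
  curves <- purrr::map(levels(g), function(lv) {
    km <- km_curve(times[g == lv], events[g == lv])
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     dplyr::select(km, "time", "survival")) |>
      dplyr::mutate(group = lv)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival") +
    ggplot2::theme_minimal()
}

#' @describeIn find_cutpoint Plot the log-rank statistic over scanned
#'   cutoffs with the selected cutpoint marked.
#' @param object A `cutpoint_result`.
#' @export
autoplot.cutpoint_result <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$cutoff,
                                            y = .data$chi_square)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "candidate cutoff", y = "log-rank chi-square") +
    ggplot2::theme_minimal()
}

#' Plot colony-class composition over timepoints
#'
#' @param summary Output of [summarize_colonies()].
#' @return A stacked-bar ggplot object.
#' @export
plot_colony_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$timepoint, y = .data$count,
                                        fill = .data$size_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "colonies", fill = "size class") +
    ggplot2::theme_minimal()
}
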
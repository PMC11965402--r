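#' Plot per-repetition range of motion
#'
#' Bar chart of ROM per repetition for one session, or grouped summary
#' points when given a multi-session ROM table.
#'
#' @param report a `session_report` (see [run_session()]), or a data
#'   frame with columns `subject` and `rom` for a cohort view.
#' @return a ggplot object.
#' @export
plot_rom <- function(report) {
  if (inherits(report, "session_report")) {
    df <- data.frame(rep = seq_along(report$rom_series),
                     rom = report$rom_series)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rep),
                                       y = .data$rom)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "repetition", y = "range of motion (deg)",
                      title = sprintf("%s (%s): ROM per repetition",
                                      report$exercise, report$side)) +
        ggplot2::theme_minimal())
  }
  stopifnot(is.data.frame(report), all(c("subject", "rom") %in%
                                         names(report)))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$subject, y = .data$rom)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "subject", y = "range of motion (deg)",
                  title = "ROM per repetition across subjects") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a per-frame classification confidence trace
#'
#' Smoothed k-NN vote counts (0..k scale) for every class over frames.
#'
#' @param trace a `classification_trace` (see [classify_sequence()]).
#' @return a ggplot object.
#' @export
plot_confidence <- function(trace) {
  stopifnot(inherits(trace, "classification_trace"))
  sm <- trace$smoothed
  df <- data.frame(
    frame = rep(trace$frame, times = ncol(sm)),
    class = rep(colnames(sm), each = nrow(sm)),
    confidence = as.vector(sm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$confidence,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, trace$k)) +
    ggplot2::labs(x = "frame", y = sprintf("confidence (0..%d)", trace$k),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a joint-angle trace with status-band edges
#'
#' @param trace an [angle_trace()].
#' @param spec optional [exercise_spec()] whose band edges are drawn as
#'   horizontal reference lines.
#' @return a ggplot object.
#' @export
plot_angle_trace <- function(trace, spec = NULL) {
  stopifnot(inherits(trace, "angle_trace"))
  p <- ggplot2::ggplot(as.data.frame(trace),
                       ggplot2::aes(x = .data$t, y = .data$theta_deg)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "joint angle (deg)") +
    ggplot2::coord_cartesian(ylim = c(0, 180)) +
    ggplot2::theme_minimal()
  if (!is.null(spec)) {
    p <- p + ggplot2::geom_hline(yintercept = spec$breaks,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
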
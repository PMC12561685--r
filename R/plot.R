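# ggplot2 displays

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Measured outputs over time, one line per output.
#' @param object an `sio_trajectory`.
#' @param what `"outputs"` or `"states"`.
#' @param ... unused.
#' @export
autoplot.sio_trajectory <- function(object, what = c("outputs", "states"), ...) {
  what <- match.arg(what)
  cols <- if (what == "outputs") attr(object, "output_names") else attr(object, "states")
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("t", cols)],
                              -"t", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = what,
                  title = paste0(attr(object, "acronym"), " trajectory")) +
    ggplot2::theme_minimal()
}

#' Plot a witness pair
#'
#' The measured outputs of the two points coincide (solid vs dashed overlay)
#' while unmeasured states and unidentifiable parameters differ — the
#' empirical picture of unidentifiability.
#' @param object an `sio_witness`.
#' @param ... unused.
#' @export
autoplot.sio_witness <- function(object, ...) {
  mk <- function(tr, which) {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(tr)[, c("t", attr(tr, "states"))],
      -"t", names_to = "series", values_to = "value")
    long$point <- which
    long
  }
  long <- dplyr::bind_rows(mk(object$trajectory_a, "point a"),
                           mk(object$trajectory_b, "point b"))
  long$measured <- ifelse(long$series %in% object$measured,
                          "measured output", "unmeasured state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series,
                                     linetype = .data$point)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measured, scales = "free_y") +
    ggplot2::labs(
      x = "time", y = "value",
      title = sprintf("%s witness pair: identical outputs, different internals",
                      object$acronym),
      subtitle = sprintf("output sup-discrepancy %.2g; distance on {%s} = %.3g",
                         object$output_discrepancy,
                         paste(object$free, collapse = ", "),
                         object$param_distance)) +
    ggplot2::theme_minimal()
}
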
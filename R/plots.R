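#' Plot a response trace
#'
#' @param object A `response_trace`.
#' @param ... Additional traces to overlay (named arguments become legend
#'   labels).
#' @return A ggplot object (normalized suppression vs time).
#' @importFrom ggplot2 autoplot
#' @method autoplot response_trace
#' @export
autoplot.response_trace <- function(object, ...) {
  extra <- list(...)
  traces <- c(list(trace = object), extra[vapply(extra, is.data.frame, logical(1))])
  if (is.null(names(traces)) || names(traces)[1] == "") names(traces)[1] <- "trace"
  df <- dplyr::bind_rows(lapply(traces, function(tr)
    tibble::tibble(time = tr$time, deltaJ = tr$deltaJ)), .id = "trace")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$deltaJ,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * J / J[dark])) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Pepperberg plot
#'
#' Saturation time against log10 flash strength for one or more genotypes,
#' with the fitted four-point regression line.
#'
#' @param ladders Named list of ladder tibbles from [tsat_ladder()].
#' @return A ggplot object.
#' @export
plot_pepperberg <- function(ladders) {
  if (is.data.frame(ladders)) ladders <- list(genotype = ladders)
  df <- dplyr::bind_rows(ladders, .id = "genotype")
  df <- dplyr::filter(df, .data$saturating)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$strength), y = .data$tsat,
                                   colour = .data$genotype)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = expression(log[10] ~ "flash strength (R* per flash)"),
                  y = expression(T[sat] ~ "(s)")) +
    ggplot2::theme_minimal()
}

#' Plot summed molecular-class trajectories
#'
#' @param classes Tibble from [class_abundances()].
#' @return A ggplot object, faceted per class.
#' @export
plot_classes <- function(classes) {
  df <- tidyr::pivot_longer(classes, -"time", names_to = "class",
                            values_to = "molecules")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$molecules)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "molecules") +
    ggplot2::theme_minimal()
}
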
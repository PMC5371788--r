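#' @rdname tidy
#' @param x A `stitch_design` object.
#' @param ... Unused.
#' @return `tidy()` returns the combined annotated candidate tibble (both
#'   strands); `glance()` a one-row design overview.
#' @export
tidy.stitch_design <- function(x, ...) {
  bind_rows(x$forward, x$reverse)
}

#' @rdname glance
#' @param x A `stitch_design` object.
#' @param ... Unused.
#' @export
glance.stitch_design <- function(x, ...) {
  tibble(
    sequence_id = x$sequence$id,
    sequence_length = x$sequence$length,
    n_forward = nrow(x$forward),
    n_forward_pass = sum(x$forward$pass),
    n_reverse = nrow(x$reverse),
    n_reverse_pass = sum(x$reverse$pass),
    n_pairs_compatible = sum(x$pairs$compatible),
    gc_percent_global = x$composition$gc_percent_global
  )
}

#' Plot the primer map of a design
#'
#' Each primer is drawn as a segment at its footprint on the input sequence,
#' forward primers above the axis and reverse primers below, passing
#' candidates solid and failing ones faded.
#'
#' @param x A `stitch_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stitch_design <- function(x, ...) {
  map <- x$map
  map$track <- ifelse(map$strand == "forward", 1, -1) *
    stats::ave(seq_len(nrow(map)), map$strand, FUN = seq_along)
  ggplot2::ggplot(map) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$track, yend = .data$track,
                   colour = .data$strand, alpha = .data$pass),
      linewidth = 2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::xlim(1, x$sequence$length) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = NULL,
                  title = paste0("Primer map: ", x$sequence$id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname autoplot
#' @export
plot_primer_map <- function(x, ...) autoplot.stitch_design(x, ...)

#' Plot a sliding-window composition profile
#'
#' GC% and AT% traces along the input sequence.
#'
#' @param x A `composition_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_profile <- function(x, ...) {
  long <- tidyr::pivot_longer(x$windows, c("gc_percent", "at_percent"),
                              names_to = "measure", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$percent,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(at_percent = "AT%",
                                              gc_percent = "GC%")) +
    ggplot2::labs(x = "window start (bp)", y = "percent", colour = NULL,
                  title = paste0("Composition: ", x$sequence_id,
                                 " (window ", x$window_size, " bp)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.composition_profile
#' @export
plot_composition <- function(x, ...) autoplot.composition_profile(x, ...)

#' Plot design summary statistics
#'
#' Horizontal bars of the minimum-average-maximum range of each primer
#' metric, per strand, over passing candidates.
#'
#' @param x A `stitch_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_design_summary <- function(x, ...) {
  s <- x$summary
  ggplot2::ggplot(s, ggplot2::aes(y = .data$metric, colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$minimum, xend = .data$maximum,
                                       yend = .data$metric),
                          position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$average),
                        position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "min / average / max", y = NULL, colour = NULL,
                  title = "Designed primer features") +
    ggplot2::theme_minimal()
}
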
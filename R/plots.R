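#' Plot a state sequence as a labeled timeline
#'
#' @param object A `rore_sequence`.
#' @param ... Unused.
#' @return A ggplot: one horizontal band per interval, labeled by state.
#' @export
autoplot.rore_sequence <- function(object, ...) {
  d <- as_tibble(object) |> mutate(domain = seq_domain(object))
  ggplot2::ggplot(d, ggplot2::aes(
    xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
    fill = .data$label
  )) +
    ggplot2::geom_rect(colour = "white", linewidth = 0.3) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0.5, label = .data$label),
      size = 3
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(
      x = "elapsed time (s)",
      title = paste(seq_domain(object), "domain")
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot an episode: therapy, response and shocks on one time axis
#'
#' @param episode A [rore_episode()].
#' @return A ggplot with one band per domain and a vertical line per shock.
#' @export
plot_episode <- function(episode) {
  bands <- bind_rows(
    as_tibble(episode$therapy) |> mutate(domain = "therapy"),
    as_tibble(episode$response) |> mutate(domain = "response")
  )
  ggplot2::ggplot(bands) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = 0, ymax = 1, fill = .data$label
      ),
      colour = "white", linewidth = 0.2
    ) +
    ggplot2::geom_vline(
      data = episode$shocks,
      ggplot2::aes(xintercept = .data$time),
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~domain, ncol = 1) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "elapsed time (s)", fill = "state") +
    ggplot2::theme_minimal()
}
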
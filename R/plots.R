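#' Plot a color time series
#'
#' One faceted panel per channel, values against time.
#'
#' @param object A `color_ts`.
#' @param channels Channels to show (default `H`, `S`, `a` — the three most
#'   pH-discriminative channels).
#' @param ... Unused.
#' @export
autoplot.color_ts <- function(object, channels = c("H", "S", "a"), ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = dplyr::any_of(channels),
                            names_to = "channel", values_to = "value")
  df$channel <- factor(df$channel, levels = channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "channel value") +
    ggplot2::theme_minimal()
}

#' Plot a stabilization detection result over its series
#'
#' Draws the detected channel's trajectory and highlights the stabilized
#' segment (from the detected frame onward) in red.
#'
#' @param series A `color_ts`.
#' @param result One-row tibble from [detect_stabilization()] or
#'   [response_time()].
#' @export
plot_stabilization <- function(series, result) {
  ch <- if (result$channel[1] %in% names(series)) result$channel[1] else "H"
  df <- tibble(t_s = series$t_s, value = series[[ch]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "time (s)", y = ch) +
    ggplot2::theme_minimal()
  if (isTRUE(result$stabilized[1])) {
    seg <- df[df$t_s >= result$stabilization_time_s[1], ]
    p <- p +
      ggplot2::geom_line(data = seg, color = "red", linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = result$stabilization_time_s[1],
                          linetype = "dashed", color = "red")
  }
  p
}

#' Scree plot of a correlation-matrix PCA
#'
#' Eigenvalues by component with the Kaiser threshold (eigenvalue 1) marked.
#'
#' @param object A `channel_pca`.
#' @param ... Unused.
#' @export
autoplot.channel_pca <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue,
                                   group = 1)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$retained), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "eigenvalue", color = "retained") +
    ggplot2::theme_minimal()
}

#' Bar chart of ReliefF feature weights
#'
#' @param object A `relief_weights` tibble.
#' @param ... Unused.
#' @export
autoplot.relief_weights <- function(object, ...) {
  df <- as_tibble(object)
  df$channel <- factor(df$channel, levels = df$channel[order(-df$weight)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "ReliefF weight") +
    ggplot2::theme_minimal()
}

#' Convergence curve of an optimization run
#'
#' @param object A `bird_opt` result.
#' @param ... Additional `bird_opt` results to overlay.
#' @export
autoplot.bird_opt <- function(object, ...) {
  extra <- purrr::keep(list(...), ~ inherits(.x, "bird_opt"))
  df <- purrr::map_dfr(c(list(object), extra), tidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$best_f,
                                   color = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best fitness") +
    ggplot2::theme_minimal()
}

#' Transition-time distributions by formulation and pH
#'
#' Box plots of response time per formulation, colored by pH.
#'
#' @param dataset A formulation-response tibble (`peg_pct`, `btb_pct`, `ph`,
#'   `response_time_s`).
#' @export
plot_transition_times <- function(dataset) {
  df <- dplyr::mutate(
    dataset,
    formulation = sprintf("P%gB%02d", .data$peg_pct,
                          round(.data$btb_pct * 100))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$formulation,
                                   y = .data$response_time_s,
                                   fill = factor(.data$ph))) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "complete transition time (s)", fill = "pH") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
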
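# ggplot2 autoplot methods.

#' Plot a heat map of a swept measure
#'
#' @param object A `phi_heatmap` from [sweep_measure()].
#' @param ... Unused.
#' @return A ggplot object (distance on x, visual field in units of pi on
#'   y, cell fill = measure value).
#' @export
autoplot.phi_heatmap <- function(object, ...) {
  measure <- attr(object, "measure")
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$zeta),
                                       y = factor(round(.data$visual_field / pi, 2)),
                                       fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance ζ (mm)", y = "visual field (π rad)",
                  fill = switch(measure, phi = "⟨Φ⟩",
                                mi = "MI (bits)", te = "ΣTE (bits)"),
                  title = sprintf("%s heat map (N = %d)", toupper(measure),
                                  attr(object, "n")))
}

#' Plot per-state Phi values
#'
#' @param object A `phi_summary` from [phi_over_series()].
#' @param ... Unused.
#' @return A ggplot bar chart of Phi per collective state, occupancy as
#'   alpha.
#' @export
autoplot.phi_summary <- function(object, ...) {
  d <- object$per_state
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$phi,
                                  alpha = .data$occupancy + 1)) +
    ggplot2::geom_col(fill = "steelblue", show.legend = FALSE) +
    ggplot2::labs(x = "collective state", y = "Φ",
                  title = sprintf("Per-state integrated information (N = %d)", object$n)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a trajectory
#'
#' @param object A `school_traj`.
#' @param ... Unused.
#' @return A ggplot of the agent paths.
#' @export
autoplot.school_traj <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = factor(.data$id))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "id")
}
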
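#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Error-surface plot of a jump simulation
#'
#' Heat map of the percentage jump-height estimation error over stature
#' and ankle-position change, faceted by true jump height. Taller bodies,
#' larger changes and lower jumps give larger errors.
#'
#' @param object A `jump_sim` tibble from [simulate_jumps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' jump_grid(stature_count = 20) |> simulate_jumps() |> autoplot()
#' @export
autoplot.jump_sim <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$change_deg, y = .data$stature_m, fill = .data$h_error_pct)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$jump_height_m),
      labeller = ggplot2::labeller(
        jump_height_m = function(h) paste0("jump ", h, " m"))) +
    ggplot2::scale_fill_viridis_c(name = "error (%)") +
    ggplot2::labs(
      x = "ankle-position change, takeoff to landing (deg)",
      y = "stature (m)",
      title = "Flight-time jump height overestimation"
    )
}

#' @rdname validate_correction
#' @param object A `correction_validation` object.
#' @export
autoplot.correction_validation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$jump_height_m, y = .data$h_corrected_m)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(
      x = "true jump height (m)",
      y = "corrected estimate (m)",
      title = sprintf("Correction validation (r² = %.4f, n = %d)",
                      object$r_squared, object$n)
    )
}
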
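#' Plot a simulation's trail dynamics
#'
#' Per-trail pheromone and departure counts over time; the signature of
#' symmetry breaking is one trail pulling away while the others decay.
#'
#' @param object An `ant_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object (facetted: pheromone and choices per step).
#' @method autoplot ant_sim
#' @export
autoplot.ant_sim <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("pheromone", "choices"), names_to = "series") |>
    dplyr::mutate(trail = factor(.data$trail))
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$step, .data$value,
                               colour = .data$trail)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time step", y = NULL, colour = "trail",
      title = sprintf("%s rule, %d ants: A = %.2f",
                      rule_label(object$config$rule),
                      object$config$colony_size, object$summary$A)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Asymmetry versus forager number across a sweep
#'
#' Scatter of per-run asymmetry against mean active forager number,
#' facetted by rule, with the null model's upper-quantile envelope overlaid
#' when supplied.
#'
#' @param table Sweep table from [run_sweep()].
#' @param envelope Optional envelope tibble from [null_envelope()].
#' @return A ggplot object.
#' @export
plot_asymmetry <- function(table, envelope = NULL) {
  p <- ggplot2::ggplot(
    dplyr::filter(table, !is.na(.data$A)),
    ggplot2::aes(.data$mean_active_foragers, .data$A)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(~rule_label) +
    ggplot2::labs(x = "mean active foragers", y = "asymmetry A") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    p <- p + ggplot2::geom_line(
      data = envelope,
      ggplot2::aes(.data$mean_active_foragers, .data$q),
      inherit.aes = FALSE, colour = "black"
    )
  }
  p
}
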
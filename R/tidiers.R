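#' Tidy a simulation's per-step records
#'
#' Returns one row per step and trail with the departures choosing that
#' trail, its pheromone, and its successful returns, plus the number of
#' ants outside the nest at that step.
#'
#' @param x An `ant_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `step`, `trail`, `choices`, `pheromone`,
#'   `returns`, `outside`.
#' @method tidy ant_sim
#' @export
tidy.ant_sim <- function(x, ...) {
  if (is.null(x$steps)) {
    stop("simulation was run with `keep_steps = FALSE`", call. = FALSE)
  }
  x$steps |>
    tidyr::pivot_longer(
      cols = -c("step", "outside"),
      names_to = c(".value", "trail"),
      names_pattern = "(choice|pheromone|returns)_(\\d+)"
    ) |>
    dplyr::mutate(trail = as.integer(.data$trail)) |>
    dplyr::rename(choices = "choice") |>
    dplyr::relocate("step", "trail", "choices", "pheromone", "returns",
                    "outside")
}

#' One-row summary of a simulation
#'
#' @param x An `ant_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: rule label, colony size, asymmetry summary.
#' @method glance ant_sim
#' @export
glance.ant_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(rule = rule_label(x$config$rule),
                   colony_size = x$config$colony_size,
                   patch_capacity = x$config$patch_capacity,
                   discrimination = x$config$discrimination,
                   seed = x$config$seed %||% NA_integer_),
    x$summary
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
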
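#' Standardized foraging asymmetry index
#'
#' Maps the share `a` of foraging activity at the most-used of `n`
#' identical food sources onto a dimensionless index
#' \deqn{A = \frac{a - 1/n}{1 - 1/n},}
#' which is 0 when the sources are used perfectly evenly (`a = 1/n`) and 1
#' when a single source receives everything (`a = 1`), independently of the
#' number of sources. With four sources, `a = 0.75` gives
#' `A = 2/3` ("approximately 0.66").
#'
#' @param a Proportion of activity at the most-preferred source, in
#'   `[1/n, 1]`.
#' @param n Number of food sources (integer >= 2).
#' @return The asymmetry index, in `[0, 1]`.
#' @examples
#' asymmetry_index(0.75, 4)
#' asymmetry_index(0.25, 4)
#' @export
asymmetry_index <- function(a, n) {
  if (!is.numeric(n) || any(n < 2) || any(n != trunc(n))) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(a) || anyNA(a) || any(a < 1 / n - 1e-12) ||
      any(a > 1 + 1e-12)) {
    stop("`a` must lie in [1/n, 1]; a smaller or larger value signals a ",
         "miscomputed share", call. = FALSE)
  }
  (a - 1 / n) / (1 - 1 / n)
}

# shared scoring core used by run_simulation() and summarize_asymmetry()
summarize_window <- function(choices, outside, window, n_trails) {
  n_steps <- nrow(choices)
  if (window < 1 || window > n_steps) {
    stop("`window` must be in [1, number of steps]", call. = FALSE)
  }
  idx <- (n_steps - window + 1L):n_steps
  totals <- colSums(choices[idx, , drop = FALSE])
  total <- sum(totals)
  if (total == 0) {
    a <- NA_real_
    A <- NA_real_
    preferred <- NA_integer_
  } else {
    a <- max(totals) / total
    A <- asymmetry_index(a, n_trails)
    preferred <- which.max(totals) # ties: lowest index
  }
  tibble::tibble(a = a, A = A, preferred_trail = as.integer(preferred),
                 n_trails = as.integer(n_trails),
                 mean_active_foragers = mean(outside[idx]),
                 total_choices = as.integer(total),
                 window = as.integer(window))
}

#' Score a simulation's foraging asymmetry
#'
#' Sums the per-trail departure choices over the trailing `window` steps,
#' takes `a` as the share of the most-chosen trail (the "most preferred"
#' source, determined within the same window; ties broken towards the
#' lowest trail index), and standardizes it with [asymmetry_index()]. Also
#' reports the mean number of ants outside the nest over the window (the
#' average active forager number). A window containing no choices at all
#' yields a missing `A` rather than 0, so inactive tiny-colony runs do not
#' bias aggregates towards symmetry.
#'
#' @param sim An `ant_sim` from [run_simulation()] (run with
#'   `keep_steps = TRUE`).
#' @param window Number of trailing steps to score; defaults to the
#'   config's `analysis_window`.
#' @return A one-row tibble with columns `a`, `A`, `preferred_trail`,
#'   `n_trails`, `mean_active_foragers`, `total_choices`, `window`.
#' @export
summarize_asymmetry <- function(sim, window = NULL) {
  stopifnot(inherits(sim, "ant_sim"))
  if (is.null(sim$steps)) {
    stop("simulation was run with `keep_steps = FALSE`; per-step records ",
         "are required", call. = FALSE)
  }
  window <- window %||% sim$config$analysis_window
  s <- sim$config$n_trails
  choices <- as.matrix(sim$steps[paste0("choice_", seq_len(s))])
  summarize_window(choices, sim$steps$outside, window, s)
}
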
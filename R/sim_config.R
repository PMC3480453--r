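#' Configuration for one colony-foraging simulation
#'
#' Bundles every model constant for a single run of the individual-based
#' simulation: a colony of `colony_size` potential foragers exploits
#' `n_trails` identical food patches over `n_steps` discrete time steps.
#' Each step, every ant in the nest leaves with probability `p_leave` and
#' picks a trail with `rule`; travel to the patch takes `travel_steps`,
#' feeding takes `feed_steps` (subject to `patch_capacity`), and the walk
#' home takes `return_steps`. Successful foragers reinforce their trail
#' (see `deposit`/`deposit_timing`), and every trail loses a fraction
#' `decay` of its pheromone at the end of each step.
#'
#' With the defaults (`p_leave = 0.01`, an 18 + 6 + 18 step trip) about
#' 25--30% of the potential foragers are outside the nest at any time, and
#' one time step corresponds to roughly 5 seconds of real foraging.
#'
#' @param colony_size Positive integer; number of potential foragers.
#' @param n_trails Number of identical patches/trails (>= 2).
#' @param p_leave Per-ant, per-step probability of leaving the nest.
#' @param travel_steps Steps to walk from nest to patch.
#' @param feed_steps Steps spent feeding at the patch.
#' @param return_steps Steps to walk home. The default mirrors
#'   `travel_steps`; the full 42-step round trip together with the mean
#'   100-step nest wait puts 42/142 = 29.6% of ants outside the nest.
#' @param deposit Pheromone laid per successful forager, in units per
#'   return-walk step when `deposit_timing = "walk"` (default; 0.02 units
#'   each of the 18 homeward steps) or as a single lump on nest arrival
#'   when `deposit_timing = "nest"`.
#' @param deposit_timing `"walk"` or `"nest"`, see above. Trail-laying on
#'   the homeward walk is the default: it is how trail-laying ants behave
#'   and it lets trail pheromone accumulate to amounts that can rival
#'   intrinsic attractiveness values `k` of the order of 2--20.
#' @param decay Fraction of each trail's pheromone lost per step.
#' @param patch_capacity Maximum ants feeding simultaneously at one patch;
#'   `Inf` for unlimited patches. Arrivals beyond capacity turn back
#'   without feeding and lay nothing.
#' @param rule A [choice_rule()]. The random null rule never lays
#'   pheromone.
#' @param discrimination Minimum detectable pheromone difference `d`
#'   (see [apply_discrimination()]); 0 = infinitely fine.
#' @param n_steps Number of time steps simulated.
#' @param analysis_window Number of trailing steps scored by
#'   [summarize_asymmetry()]; the default drops the first 100 of 1000
#'   steps so the start-up transient is not scored.
#' @param seed Integer seed for the run (optional; if `NULL` the current
#'   RNG state is used).
#' @param initial_pheromone Starting pheromone per trail (scalar or length
#'   `n_trails`); 0 by default.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(500, rule = choice_rule("ranked"), seed = 1)
#' cfg
#' @export
sim_config <- function(colony_size,
                       n_trails = 4,
                       p_leave = 0.01,
                       travel_steps = 18,
                       feed_steps = 6,
                       return_steps = travel_steps,
                       deposit = 0.02,
                       deposit_timing = c("walk", "nest"),
                       decay = 0.1,
                       patch_capacity = Inf,
                       rule = choice_rule("linear"),
                       discrimination = 0,
                       n_steps = 1000,
                       analysis_window = 900,
                       seed = NULL,
                       initial_pheromone = 0) {
  deposit_timing <- match.arg(deposit_timing)
  stop_unless <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stop_unless(is.numeric(colony_size) && length(colony_size) == 1L &&
                colony_size >= 1 && colony_size == trunc(colony_size),
              "`colony_size` must be a positive integer")
  stop_unless(is.numeric(n_trails) && n_trails >= 2 &&
                n_trails == trunc(n_trails),
              "`n_trails` must be an integer >= 2")
  stop_unless(is.numeric(p_leave) && p_leave >= 0 && p_leave <= 1,
              "`p_leave` must be a probability")
  stop_unless(is.numeric(decay) && decay >= 0 && decay <= 1,
              "`decay` must be in [0, 1]")
  stop_unless(is.numeric(deposit) && deposit >= 0, "`deposit` must be >= 0")
  for (nm in c("travel_steps", "feed_steps", "return_steps")) {
    v <- get(nm)
    stop_unless(is.numeric(v) && v >= 1 && v == trunc(v),
                paste0("`", nm, "` must be an integer >= 1"))
  }
  stop_unless(is.numeric(patch_capacity) &&
                (is.infinite(patch_capacity) ||
                   (patch_capacity >= 1 &&
                      patch_capacity == trunc(patch_capacity))),
              "`patch_capacity` must be a positive integer or Inf")
  stop_unless(inherits(rule, "choice_rule"),
              "`rule` must be a choice_rule object")
  stop_unless(is.numeric(discrimination) && discrimination >= 0,
              "`discrimination` must be >= 0")
  stop_unless(is.numeric(n_steps) && n_steps >= 1,
              "`n_steps` must be an integer >= 1")
  stop_unless(is.numeric(analysis_window) && analysis_window >= 1 &&
                analysis_window <= n_steps,
              "`analysis_window` must be in [1, n_steps]")
  stop_unless(length(initial_pheromone) %in% c(1L, n_trails) &&
                all(initial_pheromone >= 0),
              "`initial_pheromone` must be non-negative, length 1 or n_trails")
  if (!is.null(seed)) {
    stop_unless(is.numeric(seed) && length(seed) == 1L &&
                  seed == trunc(seed), "`seed` must be a single integer")
    seed <- as.integer(seed)
  }
  structure(
    list(colony_size = as.integer(colony_size),
         n_trails = as.integer(n_trails),
         p_leave = p_leave,
         travel_steps = as.integer(travel_steps),
         feed_steps = as.integer(feed_steps),
         return_steps = as.integer(return_steps),
         deposit = deposit,
         deposit_timing = deposit_timing,
         decay = decay,
         patch_capacity = patch_capacity,
         rule = rule,
         discrimination = discrimination,
         n_steps = as.integer(n_steps),
         analysis_window = as.integer(analysis_window),
         seed = seed,
         initial_pheromone = rep(as.numeric(initial_pheromone),
                                 length.out = n_trails)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  colony of %d ants, %d trails, %d steps (window %d)\n",
              x$colony_size, x$n_trails, x$n_steps, x$analysis_window))
  cat(sprintf("  rule: %s, discrimination d = %g\n",
              rule_label(x$rule), x$discrimination))
  cat(sprintf("  p_leave %g | trip %d+%d+%d steps | capacity %s\n",
              x$p_leave, x$travel_steps, x$feed_steps, x$return_steps,
              if (is.infinite(x$patch_capacity)) "unlimited"
              else format(x$patch_capacity)))
  cat(sprintf("  deposit %g/%s, decay %g/step%s\n", x$deposit,
              if (x$deposit_timing == "walk") "step walked home"
              else "trip at nest",
              x$decay,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}
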
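#' Initial colony state
#'
#' All ants start in the nest, all travel/feeding/return queues are empty
#' and trails carry `initial_pheromone` (zero by default).
#'
#' @param cfg A [sim_config()].
#' @return A `colony_state` list with elements `nest` (count), `pheromone`
#'   (per trail), and the `outbound`, `feeding`, `inbound_success`,
#'   `inbound_fail` queue matrices (trail x slot; slot 1 = just entered).
#' @export
init_state <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- cfg$n_trails
  structure(
    list(nest = cfg$colony_size,
         pheromone = cfg$initial_pheromone,
         outbound = matrix(0L, s, cfg$travel_steps),
         feeding = matrix(0L, s, cfg$feed_steps),
         inbound_success = matrix(0L, s, cfg$return_steps),
         inbound_fail = matrix(0L, s, cfg$return_steps)),
    class = "colony_state"
  )
}

state_total <- function(state) {
  state$nest + sum(state$outbound) + sum(state$feeding) +
    sum(state$inbound_success) + sum(state$inbound_fail)
}

# multinomial by sequential conditional binomials; identical RNG consumption
# to the C++ engine so whole trajectories can be compared bit-for-bit
multinom_seq <- function(n, prob) {
  s <- length(prob)
  out <- integer(s)
  rem <- 1
  left <- n
  for (i in seq_len(s - 1L)) {
    p_i <- min(max(prob[i] / rem, 0), 1)
    ni <- stats::rbinom(1L, left, p_i)
    out[i] <- ni
    left <- left - ni
    rem <- max(rem - prob[i], 1e-14)
  }
  out[s] <- left
  out
}

#' Advance the colony by one time step
#'
#' Pure-R reference implementation of the engine step, executing in order:
#' departures (each nest ant leaves with probability `p_leave` and samples a
#' trail from the current pheromone), queue advance, patch admission up to
#' free capacity (overflow turns back unsuccessful), feeding completions
#' entering the homeward walk, nest arrivals (rejoining the pool from the
#' next step), pheromone deposition by successful foragers, and evaporation.
#' [run_simulation()] uses a compiled implementation of exactly this update;
#' the two produce identical trajectories for identical seeds.
#'
#' @param state A `colony_state` from [init_state()] or a previous step.
#' @param cfg A [sim_config()].
#' @return A list with the updated `state` and a one-row `record` tibble
#'   (choices per trail, ants outside the nest, pheromone per trail,
#'   successful returns per trail).
#' @export
sim_step <- function(state, cfg) {
  stopifnot(inherits(state, "colony_state"), inherits(cfg, "sim_config"))
  s <- cfg$n_trails
  rule <- cfg$rule

  # 1. departures, using start-of-step pheromone
  n_leave <- if (state$nest > 0L && cfg$p_leave > 0) {
    stats::rbinom(1L, state$nest, cfg$p_leave)
  } else 0L
  ch <- if (n_leave > 0L) {
    pr <- preference(state$pheromone, rule, d = cfg$discrimination)
    multinom_seq(n_leave, pr)
  } else {
    integer(s)
  }
  state$nest <- state$nest - n_leave

  # 2. queues advance
  arrivals <- state$outbound[, cfg$travel_steps]
  state$outbound <- cbind(ch, state$outbound[, -cfg$travel_steps,
                                             drop = FALSE])
  done <- state$feeding[, cfg$feed_steps]
  state$feeding <- cbind(integer(s), state$feeding[, -cfg$feed_steps,
                                                   drop = FALSE])
  ret_s <- state$inbound_success[, cfg$return_steps]
  ret_f <- state$inbound_fail[, cfg$return_steps]
  state$inbound_success <-
    cbind(integer(s), state$inbound_success[, -cfg$return_steps,
                                            drop = FALSE])
  state$inbound_fail <-
    cbind(integer(s), state$inbound_fail[, -cfg$return_steps, drop = FALSE])

  # 3. patch admission; overflow turns straight back, unsuccessful
  occupancy <- rowSums(state$feeding)
  room <- if (is.infinite(cfg$patch_capacity)) arrivals else {
    pmax(cfg$patch_capacity - occupancy, 0)
  }
  admitted <- pmin(arrivals, room)
  state$feeding[, 1L] <- admitted
  state$inbound_fail[, 1L] <- arrivals - admitted

  # 4. feeding completions start the walk home
  state$inbound_success[, 1L] <- done

  # 5. nest arrivals rejoin the pool; deposition by successful foragers
  state$nest <- state$nest + sum(ret_s) + sum(ret_f)
  dep <- if (cfg$deposit_timing == "walk") {
    cfg$deposit * rowSums(state$inbound_success)
  } else {
    cfg$deposit * ret_s
  }
  # 6. evaporation closes the step
  state$pheromone <- (state$pheromone + dep) * (1 - cfg$decay)

  if (state_total(state) != cfg$colony_size) {
    stop("internal error: ant conservation violated")
  }

  record <- c(list(choices = ch,
                   outside = cfg$colony_size - state$nest,
                   pheromone = state$pheromone,
                   returns = ret_s))
  list(state = state, record = record)
}

steps_tibble <- function(choices, outside, pheromone, returns) {
  s <- ncol(choices)
  out <- tibble::tibble(step = seq_len(nrow(choices)))
  for (i in seq_len(s)) out[[paste0("choice_", i)]] <- choices[, i]
  out$outside <- as.integer(outside)
  for (i in seq_len(s)) out[[paste0("pheromone_", i)]] <- pheromone[, i]
  for (i in seq_len(s)) out[[paste0("returns_", i)]] <- returns[, i]
  out
}

#' Run a full colony-foraging simulation
#'
#' Initialises the colony, advances it `n_steps` times with a seeded random
#' stream and scores the run over the trailing `analysis_window` steps.
#' Identical configuration and seed give bit-identical results. The random
#' null rule lays no pheromone (its foragers otherwise behave identically).
#'
#' @param cfg A [sim_config()].
#' @param keep_steps Keep the per-step records (default `TRUE`); sweeps turn
#'   this off to save memory.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation built on [sim_step()]); both consume the random stream
#'   identically.
#' @return An `ant_sim` object: list with `config`, `steps` (tibble of
#'   per-step records, or `NULL`), and `summary` (one-row tibble from
#'   [summarize_asymmetry()]).
#' @examples
#' sim <- run_simulation(sim_config(500, rule = choice_rule("ranked"),
#'                                  seed = 42))
#' sim$summary
#' @export
run_simulation <- function(cfg, keep_steps = TRUE, engine = c("cpp", "r")) {
  stopifnot(inherits(cfg, "sim_config"))
  engine <- match.arg(engine)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  # the null model never reinforces trails
  deposit <- if (cfg$rule$variant == "random") 0 else cfg$deposit

  if (engine == "cpp") {
    raw <- sim_run_engine(
      colony = cfg$colony_size, n_steps = cfg$n_steps, s = cfg$n_trails,
      p_leave = cfg$p_leave, travel_steps = cfg$travel_steps,
      feed_steps = cfg$feed_steps, return_steps = cfg$return_steps,
      deposit = deposit,
      deposit_walk = as.integer(cfg$deposit_timing == "walk"),
      decay = cfg$decay, capacity = cfg$patch_capacity,
      rule = rule_code(cfg$rule), k = cfg$rule$k, x = cfg$rule$x,
      p_top = cfg$rule$p_top,
      err_uniform = as.integer(cfg$rule$error_mode == "uniform"),
      d = cfg$discrimination, pheromone0 = cfg$initial_pheromone)
  } else {
    cfg_run <- cfg
    cfg_run$deposit <- deposit
    state <- init_state(cfg_run)
    s <- cfg$n_trails
    choices <- matrix(0L, cfg$n_steps, s)
    returns <- matrix(0L, cfg$n_steps, s)
    pher <- matrix(0, cfg$n_steps, s)
    outside <- integer(cfg$n_steps)
    for (t in seq_len(cfg$n_steps)) {
      stepped <- sim_step(state, cfg_run)
      state <- stepped$state
      choices[t, ] <- stepped$record$choices
      returns[t, ] <- stepped$record$returns
      pher[t, ] <- stepped$record$pheromone
      outside[t] <- stepped$record$outside
    }
    raw <- list(choices = choices, outside = outside, pheromone = pher,
                returns = returns)
  }

  summary <- summarize_window(raw$choices, raw$outside, cfg$analysis_window,
                              cfg$n_trails)
  structure(
    list(config = cfg,
         steps = if (keep_steps) {
           steps_tibble(raw$choices, raw$outside, raw$pheromone,
                        raw$returns)
         },
         summary = summary),
    class = "ant_sim"
  )
}

#' @export
print.ant_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ant_sim> %s rule, %d ants, %d steps\n",
              rule_label(cfg$rule), cfg$colony_size, cfg$n_steps))
  cat(sprintf("  asymmetry A = %.3f (a = %.3f, preferred trail %d)\n",
              x$summary$A, x$summary$a, x$summary$preferred_trail))
  cat(sprintf("  mean active foragers = %.1f (%.1f%% of colony)\n",
              x$summary$mean_active_foragers,
              100 * x$summary$mean_active_foragers / cfg$colony_size))
  invisible(x)
}
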
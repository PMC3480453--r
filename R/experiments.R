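#' Default colony-size grid
#'
#' 25 log-spaced integer colony sizes from 5 to 2000 ants, spanning average
#' active forager numbers from about 1 to 600 with resolution at small
#' colonies. Pooled sweep statistics depend on this spacing, so every sweep
#' accepts its own `colony_sizes`.
#'
#' @return Integer vector of length 25.
#' @export
colony_sizes_default <- function() {
  c(5L, 6L, 8L, 10L, 13L, 17L, 22L, 28L, 36L, 47L, 60L, 78L, 100L, 129L,
    166L, 214L, 276L, 356L, 459L, 592L, 763L, 983L, 1267L, 1633L, 2000L)
}

rule_cell <- function(rule) {
  tibble::tibble(rule = rule$variant, k = rule$k, x = rule$x,
                 p_top = rule$p_top, error_mode = rule$error_mode)
}

#' Specify a replicated parameter sweep
#'
#' A sweep is a grid of simulation-parameter cells, each run `replicates`
#' times with deterministic per-run seeds derived from `base_seed`.
#'
#' @param grid A data frame with one row per cell. Recognised columns (all
#'   optional except `rule`): `rule` (variant name), `k`, `x`, `p_top`,
#'   `error_mode`, `colony_size`, `patch_capacity`, `discrimination`,
#'   `decay`, `deposit`, `p_leave`, `n_steps`, `analysis_window`.
#' @param replicates Runs per cell (>= 1).
#' @param base_seed Integer; per-run seeds are a deterministic function of
#'   `(base_seed, cell index, replicate index)`.
#' @param name Optional sweep name (used in manifests).
#' @param defaults A [sim_config()]-like list of default parameters applied
#'   to every cell; built from `sim_config(colony_size = 500)` by default.
#' @return A `sweep_spec` object.
#' @examples
#' spec <- sweep_spec(
#'   tidyr::crossing(rule = "linear", colony_size = c(100, 500)),
#'   replicates = 3, base_seed = 1
#' )
#' @export
sweep_spec <- function(grid, replicates = 100, base_seed = 1,
                       name = "custom", defaults = NULL) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("sweep grid must be non-empty", call. = FALSE)
  if (!"rule" %in% names(grid)) {
    stop("sweep grid needs a `rule` column", call. = FALSE)
  }
  bad <- setdiff(names(grid),
                 c("rule", "k", "x", "p_top", "error_mode", "colony_size",
                   "patch_capacity", "discrimination", "decay", "deposit",
                   "p_leave", "n_steps", "analysis_window"))
  if (length(bad)) {
    stop("unknown sweep grid column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1 || replicates > 99999) {
    stop("`replicates` must be an integer in [1, 99999]", call. = FALSE)
  }
  structure(
    list(name = name, grid = grid, replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         defaults = defaults %||% list()),
    class = "sweep_spec"
  )
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec> '%s': %d cells x %d replicates = %d runs\n",
              x$name, nrow(x$grid), x$replicates,
              nrow(x$grid) * x$replicates))
  invisible(x)
}

#' Deterministic per-run seed
#'
#' Hashes `(base_seed, cell, replicate)` into a seed below 2^31 so sweep
#' results are reproducible and independent of execution order.
#' @param base_seed,cell,replicate Integers.
#' @return A single integer seed.
#' @export
seed_for_run <- function(base_seed, cell, replicate) {
  offset <- ((base_seed %% 1048576) * 1103515245) %% 2147483647
  as.integer((offset + (cell - 1) * 1e5 + replicate) %% 2147483647)
}

cell_config <- function(cell, defaults) {
  args <- list(
    colony_size = cell$colony_size %||% defaults$colony_size %||% 500
  )
  rule_args <- list(variant = cell$rule)
  for (nm in c("k", "x", "p_top", "error_mode")) {
    v <- cell[[nm]]
    if (!is.null(v) && !is.na(v)) rule_args[[nm]] <- v
  }
  args$rule <- do.call(choice_rule, rule_args)
  for (nm in c("patch_capacity", "discrimination", "decay", "deposit",
               "p_leave", "n_steps", "analysis_window")) {
    v <- cell[[nm]] %||% defaults[[nm]]
    if (!is.null(v) && !is.na(v)) args[[nm]] <- v
  }
  do.call(sim_config, args)
}

#' Run a replicated parameter sweep
#'
#' Executes [run_simulation()] for every (cell, replicate) pair and returns
#' a tidy table with one row per run. Runs are seeded individually via
#' [seed_for_run()], so the result is reproducible and independent of
#' execution order.
#'
#' @param spec A [sweep_spec()].
#' @param progress Print a progress line per cell.
#' @return A tibble: the grid columns plus `colony_size`, `replicate`,
#'   `seed`, `rule_label`, and the scoring columns of
#'   [summarize_asymmetry()] (`a`, `A`, `preferred_trail`,
#'   `mean_active_foragers`, `total_choices`).
#' @examples
#' tbl <- run_sweep(sweep_spec(
#'   tidyr::crossing(rule = "ranked", colony_size = c(50, 500)),
#'   replicates = 2, base_seed = 7
#' ))
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- spec$grid
  cells <- seq_len(nrow(grid))
  rows <- purrr::map(cells, function(ci) {
    cell <- as.list(grid[ci, ])
    cfg0 <- tryCatch(cell_config(cell, spec$defaults),
                     error = function(e) {
                       stop("sweep cell ", ci, ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    if (progress) {
      message(sprintf("cell %d/%d: %s, colony %d", ci, nrow(grid),
                      rule_label(cfg0$rule), cfg0$colony_size))
    }
    reps <- purrr::map(seq_len(spec$replicates), function(r) {
      cfg <- cfg0
      cfg$seed <- seed_for_run(spec$base_seed, ci, r)
      sim <- run_simulation(cfg, keep_steps = FALSE)
      dplyr::bind_cols(
        tibble::as_tibble(grid[ci, setdiff(names(grid), "colony_size"),
                               drop = FALSE]),
        tibble::tibble(colony_size = cfg$colony_size,
                       rule_label = rule_label(cfg$rule),
                       replicate = r, seed = cfg$seed),
        sim$summary
      )
    })
    dplyr::bind_rows(reps)
  })
  dplyr::bind_rows(rows)
}

#' Built-in sweep designs
#'
#' Ready-made sweeps for the standard experiments:
#' * `"rules8"` — the eight treatment rules (linear; sigmoidal with
#'   k in \{0, 2, 20\} crossed with x in \{2, 3\}; ranked) over the
#'   colony-size grid.
#' * `"null"` — the random-choice null model over the colony-size grid
#'   (used for envelopes and rank-sum comparisons).
#' * `"ksweep"` — sigmoidal k = 0..6 at x = 2.
#' * `"xsweep"` — sigmoidal x = 2..5 at k = 0.
#' * `"discrimination"` — d = 0..5 for linear, sigmoidal (k=0, x=2 and 3)
#'   and ranked rules, over 20 colony sizes from 5 to 200 (500 replicates
#'   by default).
#' * `"capacity"` — patch capacity 15 vs unlimited for the same four rules
#'   plus the null.
#' * `"decay_sens"` — decay in \{0.02, 0.05, 0.1, 0.2, 0.3\} for linear and
#'   sigmoidal k=0 x=2 at coarse discrimination (d = 5).
#' * `"ranked_pref"` — ranked rule with p_top in
#'   \{0.4, 0.5, 0.6, 0.75, 0.9\}.
#'
#' @param name Preset name.
#' @param replicates Runs per cell; defaults to 100 (500 for
#'   `"discrimination"`).
#' @param colony_sizes Colony-size grid; defaults to
#'   [colony_sizes_default()] (for `"discrimination"`, 20 sizes 5--200).
#' @param base_seed Integer base seed.
#' @return A [sweep_spec()].
#' @examples
#' preset_sweep("xsweep", replicates = 5)
#' @export
preset_sweep <- function(name, replicates = NULL, colony_sizes = NULL,
                         base_seed = 1) {
  sizes <- colony_sizes %||% colony_sizes_default()
  fig6_rules <- tibble::tibble(
    rule = c("linear", "sigmoidal", "sigmoidal", "ranked"),
    k = c(NA, 0, 0, NA), x = c(NA, 2, 3, NA)
  )
  spec <- switch(name,
    rules8 = sweep_spec(
      tidyr::crossing(
        tibble::tibble(rule = c("linear", rep("sigmoidal", 6), "ranked"),
                       k = c(NA, 0, 2, 20, 0, 2, 20, NA),
                       x = c(NA, 2, 2, 2, 3, 3, 3, NA)),
        colony_size = sizes
      ),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "rules8"),
    null = sweep_spec(
      tidyr::crossing(rule = "random", colony_size = sizes),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "null"),
    ksweep = sweep_spec(
      tidyr::crossing(rule = "sigmoidal", k = 0:6, x = 2,
                      colony_size = sizes),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "ksweep"),
    xsweep = sweep_spec(
      tidyr::crossing(rule = "sigmoidal", k = 0, x = 2:5,
                      colony_size = sizes),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "xsweep"),
    discrimination = sweep_spec(
      tidyr::crossing(fig6_rules, discrimination = 0:5,
                      colony_size = colony_sizes %||%
                        unique(round(seq(5, 200, length.out = 20)))),
      replicates = replicates %||% 500, base_seed = base_seed,
      name = "discrimination"),
    capacity = sweep_spec(
      tidyr::crossing(
        dplyr::bind_rows(fig6_rules, tibble::tibble(rule = "random")),
        patch_capacity = c(15, Inf), colony_size = sizes
      ),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "capacity"),
    decay_sens = sweep_spec(
      tidyr::crossing(
        tibble::tibble(rule = c("linear", "sigmoidal"), k = c(NA, 0),
                       x = c(NA, 2)),
        decay = c(0.02, 0.05, 0.1, 0.2, 0.3), discrimination = 5,
        colony_size = sizes
      ),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "decay_sens"),
    ranked_pref = sweep_spec(
      tidyr::crossing(rule = "ranked", p_top = c(0.4, 0.5, 0.6, 0.75, 0.9),
                      colony_size = sizes),
      replicates = replicates %||% 100, base_seed = base_seed,
      name = "ranked_pref"),
    stop("unknown preset: ", name, call. = FALSE)
  )
  spec
}

#' Preset names
#' @return Character vector of names accepted by [preset_sweep()].
#' @export
preset_names <- function() {
  c("rules8", "null", "ksweep", "xsweep", "discrimination", "capacity",
    "decay_sens", "ranked_pref")
}

drop_missing_A <- function(tbl) dplyr::filter(tbl, !is.na(.data$A))

#' Upper quantile envelope of the null model
#'
#' Per colony size, the empirical upper quantile (default 95%) of the
#' asymmetry index under the random-choice null. Points above this line
#' show significantly higher asymmetry than a colony without pheromone
#' trails. Quantiles use the default linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param null_table Sweep table of random-rule runs.
#' @param prob Quantile level (default 0.95).
#' @return Tibble with `colony_size`, `mean_active_foragers` (cell mean)
#'   and `q` (the envelope value).
#' @export
null_envelope <- function(null_table, prob = 0.95) {
  if (!nrow(null_table) || !all(null_table$rule == "random")) {
    stop("`null_table` must contain (only) random-rule runs", call. = FALSE)
  }
  null_table |>
    drop_missing_A() |>
    dplyr::group_by(.data$colony_size) |>
    dplyr::summarise(
      mean_active_foragers = mean(.data$mean_active_foragers),
      q = stats::quantile(.data$A, prob, names = FALSE, type = 7),
      .groups = "drop"
    )
}

#' Rank-sum comparison of asymmetry against the null model
#'
#' Two-sample Wilcoxon rank-sum tests of the asymmetry distributions,
#' per colony size. Asymmetry is bounded and typically non-normal, hence
#' the non-parametric comparison.
#'
#' @param table Sweep table for one treatment rule.
#' @param null_table Sweep table of random-rule runs on the same
#'   colony-size grid.
#' @param alternative Passed to [stats::wilcox.test()]; default
#'   `"two.sided"`.
#' @return Tibble with `colony_size`, sample sizes, `statistic` (W) and
#'   `p_value`.
#' @export
compare_to_null <- function(table, null_table,
                            alternative = "two.sided") {
  table <- drop_missing_A(table)
  null_table <- drop_missing_A(null_table)
  sizes <- sort(unique(table$colony_size))
  purrr::map_dfr(sizes, function(cs) {
    a <- table$A[table$colony_size == cs]
    b <- null_table$A[null_table$colony_size == cs]
    if (length(a) < 5 || length(b) < 5) {
      stop("need >= 5 runs with scored asymmetry in both samples at ",
           "colony size ", cs, call. = FALSE)
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = FALSE)
    )
    tibble::tibble(colony_size = cs, n_treatment = length(a),
                   n_null = length(b),
                   mean_active_foragers = mean(
                     table$mean_active_foragers[table$colony_size == cs]),
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  })
}

#' Direction of the asymmetry--forager-number relationship
#'
#' Ordinary least-squares regression of the asymmetry index on the mean
#' active forager number across runs. The direction is the slope sign when
#' the regression is significant at `alpha`, else `"none"`.
#'
#' @param table Sweep table (typically one rule cell over colony sizes).
#' @param alpha Significance level for calling a direction.
#' @return One-row tibble: `slope`, `f_statistic`, `df1`, `df2`, `p_value`,
#'   `direction` (`"increasing"`, `"decreasing"` or `"none"`).
#' @export
asymmetry_trend <- function(table, alpha = 0.05) {
  table <- drop_missing_A(table)
  if (dplyr::n_distinct(table$mean_active_foragers) < 3) {
    stop("need >= 3 distinct forager numbers", call. = FALSE)
  }
  if (stats::var(table$A) == 0) {
    return(tibble::tibble(slope = 0, f_statistic = 0, df1 = 1,
                          df2 = nrow(table) - 2, p_value = 1,
                          direction = "none"))
  }
  fit <- stats::lm(A ~ mean_active_foragers, data = table)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  slope <- stats::coef(fit)[["mean_active_foragers"]]
  tibble::tibble(
    slope = slope,
    f_statistic = unname(fstat[1L]),
    df1 = unname(fstat[2L]), df2 = unname(fstat[3L]),
    p_value = unname(p),
    direction = if (p < alpha) {
      if (slope > 0) "increasing" else "decreasing"
    } else "none"
  )
}

#' Threshold forager number for symmetry breaking
#'
#' Scans colony sizes in ascending order and returns the first size whose
#' asymmetry distribution exceeds the null's (one-sided rank-sum test at
#' `alpha`). Colonies below the threshold forage indistinguishably from
#' the no-recruitment null; coarse trail discrimination raises the
#' threshold.
#'
#' @param table Treatment sweep table.
#' @param null_table Random-rule sweep table on the same colony-size grid.
#' @param alpha Significance level.
#' @return One-row tibble: `colony_size`, `mean_active_foragers` (NA if no
#'   size rejects).
#' @export
detect_threshold <- function(table, null_table, alpha = 0.05) {
  check_shared_grid(table, null_table)
  cmp <- compare_to_null(table, null_table, alternative = "greater")
  hit <- which(cmp$p_value < alpha)
  if (!length(hit)) {
    return(tibble::tibble(colony_size = NA_integer_,
                          mean_active_foragers = NA_real_))
  }
  cmp[hit[1L], c("colony_size", "mean_active_foragers")]
}

check_shared_grid <- function(a, b) {
  if (!setequal(unique(a$colony_size), unique(b$colony_size))) {
    stop("tables must share the same colony-size grid", call. = FALSE)
  }
  invisible(NULL)
}

#' Where limited patches damp asymmetry
#'
#' Compares capacity-limited and unlimited sweeps of the same rule:
#' returns the first colony size at which the limited runs are
#' significantly *less* asymmetric than the unlimited runs (one-sided
#' rank-sum), and the first size at which the limited runs stop differing
#' from the null after having differed at some smaller size.
#'
#' @param limited,unlimited Sweep tables of one rule with patch capacity
#'   limited and unlimited, sharing the colony-size grid.
#' @param null_table Random-rule sweep table on the same grid.
#' @param alpha Significance level.
#' @return One-row tibble: `divergence_size`, `divergence_foragers`,
#'   `convergence_size`, `convergence_foragers` (NA where not found).
#' @export
capacity_divergence <- function(limited, unlimited, null_table,
                                alpha = 0.05) {
  check_shared_grid(limited, unlimited)
  check_shared_grid(limited, null_table)
  limited <- drop_missing_A(limited)
  unlimited <- drop_missing_A(unlimited)
  sizes <- sort(unique(limited$colony_size))
  div <- NA_integer_
  div_f <- NA_real_
  for (cs in sizes) {
    a <- limited$A[limited$colony_size == cs]
    b <- unlimited$A[unlimited$colony_size == cs]
    if (length(a) < 5 || length(b) < 5) next
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "less", exact = FALSE)$p.value
    )
    if (p < alpha) {
      div <- cs
      div_f <- mean(limited$mean_active_foragers[limited$colony_size == cs])
      break
    }
  }
  cmp <- compare_to_null(limited, null_table, alternative = "greater")
  sig <- cmp$p_value < alpha
  conv <- NA_integer_
  conv_f <- NA_real_
  if (any(sig)) {
    first_sig <- which(sig)[1L]
    later <- which(!sig & seq_along(sig) > first_sig)
    if (length(later)) {
      conv <- cmp$colony_size[later[1L]]
      conv_f <- cmp$mean_active_foragers[later[1L]]
    }
  }
  tibble::tibble(divergence_size = div, divergence_foragers = div_f,
                 convergence_size = conv, convergence_foragers = conv_f)
}

#' Per-cell aggregate summaries of a sweep table
#'
#' Medians, means and 5/95% quantiles of the asymmetry index per rule cell
#' (pooled over colony sizes), plus the trend direction from
#' [asymmetry_trend()].
#'
#' @param table Sweep table from [run_sweep()].
#' @param alpha Significance level for trend directions.
#' @return A tibble with one row per rule cell.
#' @export
summarize_sweep <- function(table, alpha = 0.05) {
  table |>
    drop_missing_A() |>
    dplyr::group_by(.data$rule_label) |>
    dplyr::group_modify(function(df, key) {
      trend <- if (dplyr::n_distinct(df$mean_active_foragers) >= 3) {
        asymmetry_trend(df, alpha = alpha)
      } else {
        tibble::tibble(slope = NA_real_, p_value = NA_real_,
                       direction = NA_character_)
      }
      tibble::tibble(
        n_runs = nrow(df),
        mean_A = mean(df$A),
        median_A = stats::median(df$A),
        q05_A = stats::quantile(df$A, 0.05, names = FALSE),
        q95_A = stats::quantile(df$A, 0.95, names = FALSE),
        slope = trend$slope,
        trend_p = trend$p_value,
        direction = trend$direction
      )
    }) |>
    dplyr::ungroup()
}
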
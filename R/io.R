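# Configuration files (YAML), tidy outputs and run manifests.
# One canonical dialect: a `simulate` config is a flat YAML mapping of
# sim_config() fields with the rule nested under `rule:`; a `sweep` config
# is either `preset: <name>` plus options, or an explicit `grid:` list.
# Unknown keys are errors, not warnings.

output_schema_version <- "1"

config_keys_sim <- c("colony_size", "n_trails", "p_leave", "travel_steps",
                     "feed_steps", "return_steps", "deposit",
                     "deposit_timing", "decay", "patch_capacity",
                     "discrimination", "n_steps", "analysis_window",
                     "seed", "rule")
config_keys_rule <- c("variant", "k", "x", "p_top", "error_mode")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

rule_from_list <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- list(variant = x)
  check_keys(x, config_keys_rule, "rule")
  if (is.null(x$variant)) stop("rule needs a `variant`", call. = FALSE)
  known <- c("random", "linear", "sigmoidal", "ranked")
  if (!x$variant %in% known) {
    stop("unknown rule `variant`: \"", x$variant, "\" (expected one of ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  }
  do.call(choice_rule, x)
}

rule_to_list <- function(rule) {
  switch(rule$variant,
    random = list(variant = "random"),
    linear = list(variant = "linear"),
    sigmoidal = list(variant = "sigmoidal", k = rule$k, x = rule$x),
    ranked = list(variant = "ranked", p_top = rule$p_top,
                  error_mode = rule$error_mode)
  )
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file of [sim_config()] fields; the rule is a
#'   nested mapping (`variant`, and `k`/`x`/`p_top`/`error_mode` as
#'   needed). Unknown keys raise an error naming the offending key.
#' @param overrides Named list applied on top of the file's values.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_keys_sim, "config")
  check_keys(overrides, config_keys_sim, "override")
  raw[names(overrides)] <- overrides
  if (!is.null(raw$patch_capacity) &&
      identical(raw$patch_capacity, "unlimited")) {
    raw$patch_capacity <- Inf
  }
  if (is.null(raw$colony_size)) {
    stop("config must set `colony_size`", call. = FALSE)
  }
  if (!is.null(raw$rule)) raw$rule <- rule_from_list(raw$rule)
  do.call(sim_config, raw)
}

#' Serialize a simulation configuration
#'
#' Inverse of [read_sim_config()]: `read_sim_config(write_sim_config(cfg))`
#' reproduces `cfg` on all documented keys.
#'
#' @param cfg A [sim_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$initial_pheromone <- NULL
  x$rule <- rule_to_list(cfg$rule)
  if (is.infinite(x$patch_capacity)) x$patch_capacity <- "unlimited"
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Everything needed to bit-reproduce a run or sweep: package version,
#' schema version, the fully resolved configuration, the base seed and the
#' per-run seed derivation rule.
#'
#' @param config Resolved configuration (a [sim_config()] or
#'   [sweep_spec()]).
#' @param base_seed Integer seed the run(s) derive from.
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(config, base_seed) {
  resolved <- if (inherits(config, "sim_config")) {
    x <- unclass(config)
    x$rule <- rule_to_list(config$rule)
    if (is.infinite(x$patch_capacity)) x$patch_capacity <- "unlimited"
    x
  } else if (inherits(config, "sweep_spec")) {
    list(name = config$name, replicates = config$replicates,
         grid = lapply(seq_len(nrow(config$grid)),
                       function(i) as.list(config$grid[i, ])))
  } else {
    stop("`config` must be a sim_config or sweep_spec", call. = FALSE)
  }
  list(
    artifact = "antsym",
    version = as.character(utils::packageVersion("antsym")),
    schema_version = output_schema_version,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    base_seed = base_seed,
    seed_rule = paste("per-run seed = ((base_seed %% 2^20) * 1103515245 +",
                      "(cell - 1) * 1e5 + replicate) %% (2^31 - 1)"),
    config = resolved
  )
}

#' Write simulation outputs to a directory
#'
#' Writes `steps.csv` (tidy per-step records), `summary.json` and
#' `manifest.json`.
#'
#' @param sim An `ant_sim` from [run_simulation()] with per-step records.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(sim, dir) {
  stopifnot(inherits(sim, "ant_sim"))
  if (is.null(sim$steps)) {
    stop("simulation was run with `keep_steps = FALSE`", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$steps, file.path(dir, "steps.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(sim$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run_manifest(sim$config,
                                    sim$config$seed %||% NA_integer_),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write sweep outputs to a directory
#'
#' Writes `runs.csv` (one row per run), `aggregate.json` (per-cell medians,
#' quantiles and trend directions from [summarize_sweep()]) and
#' `manifest.json`.
#'
#' @param table Sweep table from [run_sweep()].
#' @param spec The [sweep_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_result <- function(table, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- table
  if ("patch_capacity" %in% names(tbl)) {
    tbl$patch_capacity <- ifelse(is.infinite(tbl$patch_capacity),
                                 "unlimited", tbl$patch_capacity)
  }
  utils::write.csv(tbl, file.path(dir, "runs.csv"), row.names = FALSE)
  jsonlite::write_json(summarize_sweep(table),
                       file.path(dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(run_manifest(spec, spec$base_seed),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a sweep configuration from YAML
#'
#' Either `preset: <name>` with optional `replicates`, `colony_sizes` and
#' `base_seed`, or an explicit `grid:` (list of cell mappings) with
#' `replicates` and `base_seed`.
#'
#' @param path Path to the YAML file.
#' @return A [sweep_spec()].
#' @export
read_sweep_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("preset", "grid", "replicates", "colony_sizes",
                    "base_seed", "name"), "sweep config")
  if (!is.null(raw$preset)) {
    preset_sweep(raw$preset, replicates = raw$replicates,
                 colony_sizes = raw$colony_sizes,
                 base_seed = raw$base_seed %||% 1)
  } else if (!is.null(raw$grid)) {
    grid <- dplyr::bind_rows(lapply(raw$grid, tibble::as_tibble))
    sweep_spec(grid, replicates = raw$replicates %||% 100,
               base_seed = raw$base_seed %||% 1,
               name = raw$name %||% "custom")
  } else {
    stop("sweep config needs `preset` or `grid`", call. = FALSE)
  }
}
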
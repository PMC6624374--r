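## Run configuration: a single versioned YAML document holding the forcing,
## group-spec overrides, simulation, scenario and classification blocks.
## Unknown keys are rejected field-by-field; dump(load(x)) is the identity
## with all defaults materialised.

CONFIG_VERSION <- 1L

.config_schema <- list(
  forcing = c("latitude", "peak_noon_irradiance"),
  simulation = c("dt", "season_start_day", "season_end_day",
                 "analysis_start_day", "layer_depth", "k_s",
                 "record_interval", "seed_biomass", "initial_doc",
                 "initial_quota_fraction", "extinction_floor"),
  scenario = c("fish_abundance", "NO3_0", "NH4_0", "k_bg",
               "bioavailability", "b1_input_multiplier", "label"),
  classification = c("quota_threshold", "poor_fraction", "rich_fraction"),
  grid = c("n_fish", "n_nutrient", "n_kbg"))

#' Default run configuration
#'
#' Fully materialised configuration list: forcing, simulation, scenario,
#' classification and grid blocks, plus an (empty by default) `groups` block
#' of per-group parameter overrides applied on top of
#' [baltic_default_specs()].
#'
#' @return A list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    version = CONFIG_VERSION,
    forcing = list(latitude = 56.93, peak_noon_irradiance = 1.0),
    simulation = unclass(sim_config()),
    scenario = unclass(scenario())[c("fish_abundance", "NO3_0", "NH4_0",
                                     "k_bg", "bioavailability",
                                     "b1_input_multiplier", "label")],
    classification = unclass(classification_rule()),
    grid = list(n_fish = 5L, n_nutrient = 7L, n_kbg = 6L),
    groups = list()),
    class = "run_config")
}

.validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  known_top <- c("version", names(.config_schema), "groups")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$version) && cfg$version != CONFIG_VERSION)
    stop("unsupported config version: ", cfg$version)
  for (blk in names(.config_schema)) {
    if (is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), .config_schema[[blk]])
    if (length(bad))
      stop("unknown key(s) in '", blk, "' block: ",
           paste(bad, collapse = ", "))
  }
  # constructors perform the numeric validation
  merged <- .merge_config(default_config(), cfg)
  do.call(light_forcing, merged$forcing)
  do.call(sim_config, merged$simulation)
  do.call(scenario, merged$scenario)
  do.call(classification_rule, merged$classification)
  with(merged$grid, {
    if (n_fish < 1 || n_nutrient < 1 || n_kbg < 1)
      stop("grid level counts must be >= 1")
  })
  if (length(merged$groups))
    apply_spec_overrides(baltic_default_specs(), merged$groups)
  merged
}

.merge_config <- function(base, override) {
  for (blk in names(override)) {
    if (blk %in% c("version")) next
    if (blk == "groups") { base$groups <- override$groups; next }
    for (key in names(override[[blk]]))
      base[[blk]][[key]] <- override[[blk]][[key]]
  }
  base
}

#' Load / dump a run configuration
#'
#' `load_config()` reads a YAML configuration, validates it against the
#' schema (unknown keys are rejected by name) and returns it with all
#' defaults materialised; `dump_config()` writes a configuration back out.
#' `dump_config()` followed by `load_config()` is the identity.
#'
#' @param path File path.
#' @param config A `run_config` (or partial configuration list).
#' @return `load_config()` returns a `run_config`; `dump_config()` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- .validate_config(raw)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @export
dump_config <- function(config, path) {
  cfg <- .validate_config(unclass(config))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Materialise the model objects described by a configuration
#'
#' @param config A `run_config` (e.g. from [load_config()] or
#'   [default_config()]).
#' @return List with elements `forcing`, `config` (a [sim_config()]),
#'   `scenario`, `rule`, `specs` and `grid_levels`.
#' @export
config_objects <- function(config) {
  cfg <- .validate_config(unclass(config))
  list(forcing = do.call(light_forcing, cfg$forcing),
       config = do.call(sim_config, cfg$simulation),
       scenario = do.call(scenario, cfg$scenario),
       rule = do.call(classification_rule, cfg$classification),
       specs = baltic_default_specs(
         overrides = if (length(cfg$groups)) cfg$groups else NULL),
       grid_levels = cfg$grid)
}
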
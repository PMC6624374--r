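#' Phosphate from nitrogen at Redfield stoichiometry
#'
#' Initial phosphate is derived from the total initial nitrogen at the
#' Redfield N:P ratio of 16:1.
#'
#' @param NO3_0,NH4_0 Initial nitrate and ammonium, mmol m^-3 (1 umol/l ==
#'   1 mmol m^-3).
#' @return Initial PO4, mmol m^-3.
#' @export
redfield_phosphorus <- function(NO3_0, NH4_0) {
  if (any(NO3_0 < 0) || any(NH4_0 < 0)) stop("nutrient inputs must be >= 0")
  (NO3_0 + NH4_0) / 16
}

#' One scenario: a point of the environmental parameter cube
#'
#' A scenario fixes the three swept environmental factors (planktivorous fish
#' abundance, initial nutrient concentrations, background light attenuation)
#' plus the two sensitivity axes (B1 bioavailability and the source-rate
#' multiplier). Initial phosphate is always derived from nitrogen via
#' [redfield_phosphorus()].
#'
#' @param fish_abundance Individuals m^-3. Default 0.007 (mid-range).
#' @param NO3_0,NH4_0 Initial nitrate/ammonium, mmol m^-3. Defaults are the
#'   midpoints of the low (2.01, 0.93) and high (30, 7) endpoints.
#' @param k_bg Background attenuation, m^-1. Default 0.14 (mid-range).
#' @param bioavailability Fraction of ingested B1 absorbed (default 0.15).
#' @param b1_input_multiplier Multiplier on the B1 source rate of producers
#'   and bacteria (default 1).
#' @param label Scenario identifier.
#' @return An object of class `scenario`.
#' @export
scenario <- function(fish_abundance = 0.007, NO3_0 = 16.005, NH4_0 = 3.965,
                     k_bg = 0.14, bioavailability = 0.15,
                     b1_input_multiplier = 1.0, label = "default") {
  if (fish_abundance < 0) stop("`fish_abundance` must be >= 0")
  if (NO3_0 < 0 || NH4_0 < 0) stop("nutrients must be >= 0")
  if (k_bg <= 0) stop("`k_bg` must be > 0")
  if (bioavailability < 0 || bioavailability > 1)
    stop("`bioavailability` must lie in [0, 1]")
  if (b1_input_multiplier < 0) stop("`b1_input_multiplier` must be >= 0")
  structure(list(fish_abundance = fish_abundance, NO3_0 = NO3_0,
                 NH4_0 = NH4_0, PO4_0 = redfield_phosphorus(NO3_0, NH4_0),
                 k_bg = k_bg, bioavailability = bioavailability,
                 b1_input_multiplier = b1_input_multiplier,
                 label = as.character(label)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$label, ": fish ", x$fish_abundance,
      " ind m^-3, NO3 ", x$NO3_0, ", NH4 ", x$NH4_0, ", PO4 ",
      signif(x$PO4_0, 4), " mmol m^-3, k_bg ", x$k_bg, " m^-1, b ",
      x$bioavailability, ", B1 source x", x$b1_input_multiplier, "\n",
      sep = "")
  invisible(x)
}

## Printed extremes of the swept factors.
FISH_RANGE <- c(0.004, 0.01)       # ind m^-3
NO3_RANGE <- c(2.01, 30)           # mmol m^-3
NH4_RANGE <- c(0.93, 7)            # mmol m^-3
KBG_RANGE <- c(0.04, 0.24)         # m^-1

#' Construct the 3-factor scenario cube
#'
#' Evenly spaced levels spanning fish abundance 0.004-0.01 ind m^-3, total
#' nitrogen from the very-low (NO3 2.01 + NH4 0.93) to the very-high (30 + 7)
#' endpoints with NO3 and NH4 interpolated linearly between the endpoint
#' pairs, and background attenuation 0.04-0.24 m^-1. The Cartesian product is
#' returned with stable, deterministic ids. The production grid is 5 x 7 x 6;
#' a desk-scale grid of 3 x 5 x 5 is used for scaled-down runs.
#'
#' @param n_fish,n_nutrient,n_kbg Number of levels per axis (>= 1). A single
#'   level sits at the low end of its range.
#' @param bioavailability,b1_input_multiplier Passed to every scenario.
#' @return List of [scenario()] objects with class `scenario_grid`.
#' @export
scenario_grid <- function(n_fish = 5, n_nutrient = 7, n_kbg = 6,
                          bioavailability = 0.15,
                          b1_input_multiplier = 1.0) {
  if (n_fish < 1 || n_nutrient < 1 || n_kbg < 1)
    stop("axis level counts must be >= 1")
  lev <- function(r, n) if (n == 1) r[1] else seq(r[1], r[2], length.out = n)
  fish <- lev(FISH_RANGE, n_fish)
  no3 <- lev(NO3_RANGE, n_nutrient)
  nh4 <- lev(NH4_RANGE, n_nutrient)
  kbg <- lev(KBG_RANGE, n_kbg)
  out <- list()
  idx <- 0L
  for (i in seq_len(n_fish)) for (j in seq_len(n_nutrient))
    for (l in seq_len(n_kbg)) {
      idx <- idx + 1L
      out[[idx]] <- scenario(
        fish_abundance = fish[i], NO3_0 = no3[j], NH4_0 = nh4[j],
        k_bg = kbg[l], bioavailability = bioavailability,
        b1_input_multiplier = b1_input_multiplier,
        label = sprintf("f%d_n%d_k%d", i, j, l))
    }
  structure(out, class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid> with", length(x), "scenarios\n")
  invisible(x)
}

#' Manifest of a scenario grid
#'
#' @param grid A `scenario_grid` (or plain list of scenarios).
#' @return Data frame with one row per scenario.
#' @export
grid_manifest <- function(grid) {
  do.call(rbind, lapply(grid, function(s)
    data.frame(label = s$label, fish_abundance = s$fish_abundance,
               NO3_0 = s$NO3_0, NH4_0 = s$NH4_0, PO4_0 = s$PO4_0,
               total_N = s$NO3_0 + s$NH4_0, k_bg = s$k_bg,
               bioavailability = s$bioavailability,
               b1_input_multiplier = s$b1_input_multiplier)))
}

#' Sweep one sensitivity parameter around a base scenario
#'
#' Copies of `base` with either the bioavailability (5-20% is the studied
#' range) or the B1 source-rate multiplier swept; everything else is fixed
#' and `base` is not modified.
#'
#' @param base A [scenario()].
#' @param parameter `"bioavailability"` or `"b1_input_multiplier"`.
#' @param values Numeric vector of parameter values.
#' @return List of scenarios (possibly empty).
#' @export
sensitivity_axis <- function(base,
                             parameter = c("bioavailability",
                                           "b1_input_multiplier"),
                             values) {
  stopifnot(inherits(base, "scenario"))
  parameter <- match.arg(parameter)
  if (parameter == "bioavailability" &&
      (any(values < 0) || any(values > 1)))
    stop("bioavailability values must lie in [0, 1]")
  if (parameter == "b1_input_multiplier" && any(values < 0))
    stop("multiplier values must be >= 0")
  lapply(seq_along(values), function(i) {
    s <- base
    s[[parameter]] <- values[i]
    s$label <- sprintf("%s_%s=%g", base$label, parameter, values[i])
    s
  })
}
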
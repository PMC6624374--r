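#' Classification rule for fish vitamin B1 status
#'
#' A scenario is B1-poor when the fish quota drops below the threshold (the
#' average level recorded in Baltic clupeids, 6.41e-11 umol B1 per umol C)
#' for more than `poor_fraction` of the analysis window, and B1-rich when it
#' stays above the threshold for more than `rich_fraction` of the window.
#' All comparisons are strict; boundary cases fall to `intermediate`.
#'
#' @param quota_threshold Threshold quota, umol B1 per umol C.
#' @param poor_fraction Fraction of days below threshold beyond which a
#'   scenario is B1-poor (default 0.30).
#' @param rich_fraction Fraction of days above threshold beyond which a
#'   scenario is B1-rich (default 0.70).
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(quota_threshold = 6.41e-11,
                                poor_fraction = 0.30,
                                rich_fraction = 0.70) {
  if (quota_threshold <= 0) stop("`quota_threshold` must be > 0")
  if (poor_fraction <= 0 || poor_fraction > 1)
    stop("`poor_fraction` must lie in (0, 1]")
  if (rich_fraction <= 0 || rich_fraction > 1)
    stop("`rich_fraction` must lie in (0, 1]")
  structure(list(quota_threshold = quota_threshold,
                 poor_fraction = poor_fraction,
                 rich_fraction = rich_fraction),
            class = "classification_rule")
}

#' Classify a daily fish-quota series
#'
#' @param days Integer days of year of the series.
#' @param fish_quota Daily fish B1 quota, umol B1 per umol C.
#' @param rule A [classification_rule()].
#' @param window_start,window_end Analysis window (days of year, inclusive).
#' @return An object of class `scenario_classification` with fields
#'   `fraction_days_below`, `label`, `window_start`, `window_end`,
#'   `n_days`.
#' @export
classify_series <- function(days, fish_quota, rule = classification_rule(),
                            window_start = 152, window_end = 274) {
  if (length(days) != length(fish_quota))
    stop("`days` and `fish_quota` must have equal length")
  if (min(days) > window_start || max(days) < window_end)
    stop("series does not cover the analysis window ", window_start, "-",
         window_end)
  w <- days >= window_start & days <= window_end
  q <- fish_quota[w]
  frac <- mean(q < rule$quota_threshold)
  label <- if (frac > rule$poor_fraction) "b1_poor"
           else if ((1 - frac) > rule$rich_fraction) "b1_rich"
           else "intermediate"
  structure(list(fraction_days_below = frac, label = label,
                 window_start = window_start, window_end = window_end,
                 n_days = sum(w)),
            class = "scenario_classification")
}

#' Classify a simulation by fish vitamin B1 status
#'
#' Computes the fraction of analysis-window days on which the fish B1 quota
#' lies strictly below the threshold and labels the scenario `b1_poor`,
#' `b1_rich` or `intermediate`. The B1-poor condition takes precedence if
#' both conditions were ever to hold simultaneously.
#'
#' @param result A `b1_sim` object whose web contains a `fish` group.
#' @param rule A [classification_rule()].
#' @return A `scenario_classification`.
#' @export
classify <- function(result, rule = classification_rule()) {
  stopifnot(inherits(result, "b1_sim"))
  if (!"fish" %in% colnames(result$quota))
    stop("result has no 'fish' group to classify")
  classify_series(result$days, result$quota[, "fish"], rule,
                  window_start = result$config$analysis_start_day,
                  window_end = result$config$season_end_day)
}

#' @export
print.scenario_classification <- function(x, ...) {
  cat("<scenario_classification>", x$label, "- fraction of days below",
      "threshold:", round(x$fraction_days_below, 4), "over", x$n_days,
      "days\n")
  invisible(x)
}

# population standard deviation; CV undefined (NA) for zero-mean series
.cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Summary statistics over the analysis window
#'
#' Mean mesozooplankton biomass; coefficients of variation (population
#' standard deviation over mean) of ciliate, microalgae, picoalgae and
#' mesozooplankton biomass; mean fraction of producer biomass in picoalgae;
#' and medians of depth-averaged light, DIN and DIP -- all over daily values
#' in the analysis window.
#'
#' @param result A `b1_sim` run of the full food web.
#' @return Named list of class `summary_stats`.
#' @export
summarize_run <- function(result) {
  stopifnot(inherits(result, "b1_sim"))
  w <- result$days >= result$config$analysis_start_day &
    result$days <= result$config$season_end_day
  bm <- result$biomass[w, , drop = FALSE]
  dis <- result$dissolved[w, , drop = FALSE]
  li <- result$light[w, , drop = FALSE]
  col <- function(name) if (name %in% colnames(bm)) bm[, name] else NULL
  pico <- col("picoalgae"); nano <- col("nanoalgae")
  micro <- col("microalgae"); meso <- col("mesozooplankton")
  cil <- col("ciliates")
  prod_tot <- if (!is.null(pico)) pico +
    (if (is.null(nano)) 0 else nano) +
    (if (is.null(micro)) 0 else micro) else NULL
  out <- list(
    mean_mesozoo_biomass = if (is.null(meso)) NA_real_ else mean(meso),
    cv_ciliates = if (is.null(cil)) NA_real_ else .cv(cil),
    cv_microalgae = if (is.null(micro)) NA_real_ else .cv(micro),
    cv_picoalgae = if (is.null(pico)) NA_real_ else .cv(pico),
    cv_mesozoo = if (is.null(meso)) NA_real_ else .cv(meso),
    picoalgae_biomass_fraction =
      if (is.null(prod_tot)) NA_real_ else mean(pico / prod_tot),
    median_depth_avg_light = stats::median(li[, "mean_irradiance"],
                                           na.rm = TRUE),
    median_DIN = stats::median(dis[, "NO3"] + dis[, "NH4"]),
    median_DIP = stats::median(dis[, "PO4"]))
  class(out) <- c("summary_stats", "list")
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats>\n")
  for (f in names(x)) cat(sprintf("  %-28s %.4g\n", f, x[[f]]))
  invisible(x)
}

#' Analytic trophic decay chain
#'
#' A pool of a compound entering the base of the food web and passing `n`
#' consumer levels, each absorbing a fraction `b` (bioavailability), decays
#' as `b^n`: the surviving fraction is `b^n` and the fold reduction `b^-n`.
#' With b = 0.15 a pool from picoalgae (four consumer levels to fish:
#' nanoflagellates, ciliates, mesozooplankton, fish) retains ~0.5 permille
#' (a ~2000-fold drop), a pool from microalgae (two levels) ~2%.
#'
#' @param b Bioavailability in (0, 1].
#' @param n Number of consumer levels (non-negative integer).
#' @return An object of class `decay_chain` with `surviving_fraction` and
#'   `fold_reduction` (NA when `b = 0` with `n > 0`).
#' @export
decay_chain <- function(b, n) {
  if (b < 0 || b > 1) stop("`b` must lie in [0, 1]")
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer")
  surviving <- b^n
  fold <- if (b == 0 && n > 0) NA_real_ else b^-n
  structure(list(b = b, n = n, surviving_fraction = surviving,
                 fold_reduction = fold),
            class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat(sprintf(paste0("<decay_chain> b = %g over %d consumer level(s): ",
                     "%.4g surviving (%.4g-fold reduction)\n"),
              x$b, x$n, x$surviving_fraction, x$fold_reduction))
  invisible(x)
}

#' Number of consumer levels from an entry group to fish
#'
#' In the default web a compound from picoalgae or bacteria passes four
#' consumer levels to reach fish (nanoflagellates, ciliates,
#' mesozooplankton, fish); from nanoalgae three; from microalgae two.
#'
#' @param entry_group Name of the producing group.
#' @return Integer number of consumer levels.
#' @export
consumer_levels_to_fish <- function(entry_group) {
  lv <- c(bacteria = 4L, picoalgae = 4L, nanoalgae = 3L, microalgae = 2L,
          nanoflagellates = 3L, ciliates = 2L, mesozooplankton = 1L)
  if (!entry_group %in% names(lv))
    stop("no path from '", entry_group, "' to fish")
  unname(lv[entry_group])
}

#' Tabulate classifications and summaries over a scenario cube
#'
#' @param classifications List of `scenario_classification` objects.
#' @param summaries List of `summary_stats` of the same length.
#' @param manifest Data frame from [grid_manifest()] keying each scenario by
#'   its environmental factors.
#' @return Data frame of class `cube_report`, one row per scenario, with the
#'   classification label, the fraction of B1-poor days, all summary columns
#'   and a soft flag `pico_fraction_above_median` (is the scenario's
#'   picoalgae biomass fraction above the grid median?).
#' @export
cube_report <- function(classifications, summaries, manifest) {
  if (length(classifications) != length(summaries) ||
      length(classifications) != nrow(manifest))
    stop("classifications, summaries and manifest must align")
  if (nrow(manifest) == 0) {
    out <- cbind(manifest, label = character(0))
    class(out) <- c("cube_report", class(out))
    return(out)
  }
  if (anyDuplicated(manifest$label))
    stop("duplicate scenario ids in manifest")
  cls <- data.frame(
    label_class = vapply(classifications, `[[`, character(1), "label"),
    fraction_days_below = vapply(classifications, `[[`, numeric(1),
                                 "fraction_days_below"))
  sm <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(unclass(s))))
  out <- cbind(manifest, cls, sm)
  med <- stats::median(out$picoalgae_biomass_fraction, na.rm = TRUE)
  out$pico_fraction_above_median <- out$picoalgae_biomass_fraction > med
  class(out) <- c("cube_report", class(out))
  out
}

#' Run, classify and summarise every scenario of a grid
#'
#' @param grid A `scenario_grid` (or list of scenarios).
#' @param specs,config,forcing Passed to [run_scenario()].
#' @param rule A [classification_rule()].
#' @param verbose Print one progress line per scenario to stderr.
#' @return A [cube_report()] data frame.
#' @export
run_grid <- function(grid, specs = baltic_default_specs(),
                     config = sim_config(), forcing = light_forcing(),
                     rule = classification_rule(), verbose = FALSE) {
  cls <- vector("list", length(grid))
  sm <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- run_scenario(grid[[i]], specs = specs, config = config,
                        forcing = forcing)
    cls[[i]] <- classify(res, rule)
    sm[[i]] <- summarize_run(res)
    if (verbose)
      message(sprintf("[%d/%d] %s -> %s", i, length(grid),
                      grid[[i]]$label, cls[[i]]$label))
  }
  cube_report(cls, sm, grid_manifest(grid))
}
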
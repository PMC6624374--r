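#' Simulation configuration
#'
#' Time is measured in continuous days since 1 January 00:00 local solar
#' time. The vegetative season runs from 30 March (day 89) to 1 October
#' (day 274); the first two months are excluded from analysis, which starts
#' 1 June (day 152). The integrator is explicit Euler with proportional flux
#' limiting so that no pool can be driven negative within a step.
#'
#' @param dt Time step in days; must divide one day evenly. Default 0.02.
#' @param season_start_day,season_end_day Integer days of year bounding the
#'   simulated season.
#' @param analysis_start_day First day of year of the analysis window.
#' @param layer_depth Mixed-layer depth H, m.
#' @param k_s Self-shading coefficient, m^2 per mg algal C.
#' @param record_interval Recording interval in whole days.
#' @param seed_biomass Initial biomass of each plankton group, umol C m^-3.
#' @param initial_doc Initial DOC, mmol C m^-3.
#' @param initial_quota_fraction Initial B1 quota as a fraction of each
#'   group's `q_max` ("picomolar" start; default 0.01).
#' @param extinction_floor Biomass floor, umol C m^-3, below which grazing
#'   cannot push a population (avoids hard zeros while permitting deep
#'   troughs).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.02, season_start_day = 89,
                       season_end_day = 274, analysis_start_day = 152,
                       layer_depth = 10, k_s = 5e-5, record_interval = 1,
                       seed_biomass = 5, initial_doc = 5,
                       initial_quota_fraction = 0.01,
                       extinction_floor = 1e-2) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.1)
    stop("`dt` must lie in (0, 0.1]")
  spd <- 1 / dt
  if (abs(spd - round(spd)) > 1e-9)
    stop("`dt` must divide one day evenly (1/dt integer)")
  if (!(season_start_day < analysis_start_day &&
        analysis_start_day < season_end_day))
    stop("need season_start_day < analysis_start_day < season_end_day")
  if (layer_depth <= 0) stop("`layer_depth` must be > 0")
  if (k_s < 0) stop("`k_s` must be >= 0")
  if (record_interval < 1 || record_interval != round(record_interval))
    stop("`record_interval` must be a positive whole number of days")
  if (seed_biomass <= 0 || initial_doc < 0 || extinction_floor < 0)
    stop("invalid initial conditions")
  if (initial_quota_fraction < 0 || initial_quota_fraction > 1)
    stop("`initial_quota_fraction` must lie in [0, 1]")
  structure(list(dt = dt, season_start_day = season_start_day,
                 season_end_day = season_end_day,
                 analysis_start_day = analysis_start_day,
                 layer_depth = layer_depth, k_s = k_s,
                 record_interval = record_interval,
                 seed_biomass = seed_biomass, initial_doc = initial_doc,
                 initial_quota_fraction = initial_quota_fraction,
                 extinction_floor = extinction_floor),
            class = "sim_config")
}

# Compile specs + scenario + config into flat vectors for the inner loop.
build_engine <- function(specs, scenario, config, forcing) {
  stopifnot(inherits(specs, "foodweb_specs"), inherits(config, "sim_config"))
  n <- length(specs)
  nm <- names(specs)
  g <- function(field, default = NA_real_) {
    v <- vapply(specs, function(s) {
      x <- s[[field]]
      if (is.null(x) || length(x) != 1 || is.na(x)) default else as.numeric(x)
    }, numeric(1))
    unname(v)
  }
  role <- vapply(specs, `[[`, character(1), "role")
  preyM <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) preyM[i, specs[[i]]$prey] <- TRUE
  list(n = n, names = nm, role = role,
       prod_idx = which(role == "producer"),
       bact_idx = which(role == "heterotrophic_bacteria"),
       alg_idx = which(role == "producer"),
       cons = role %in% c("consumer", "fish"),
       fish = role == "fish",
       preyM = preyM,
       mu_max = g("mu_max", 0), K_N = g("K_N", 1), K_P = g("K_P", 1),
       K_I = g("K_I", 1), K_DOC = g("K_DOC", 1),
       clearance = g("clearance", 0), Imax = g("I_max", 0),
       gge = g("gge", 0.3), metab = g("metabolic_rate", 0),
       basal = g("basal_respiration", 0),
       qmax = g("q_max", 0), ind_mass = g("individual_mass", 0),
       dt = config$dt, H = config$layer_depth, k_s = config$k_s,
       floor = config$extinction_floor,
       k_bg = scenario$k_bg, b = scenario$bioavailability,
       mult = scenario$b1_input_multiplier,
       fish_abundance = scenario$fish_abundance,
       forcing = forcing)
}

# One explicit-Euler step from pool vectors; returns updated pools plus
# ledger increments. All fluxes are evaluated at the incoming state and
# proportionally limited so no pool is exhausted within the step; every
# sub-step conserves N and P exactly by construction.
.step_once <- function(bio, b1, no3, nh4, po4, doc, I0, eng) {
  dt <- eng$dt
  n <- eng$n

  ## (1) light
  W_PP <- MG_C_PER_UMOL * sum(bio[eng$alg_idx])
  k <- eng$k_s * W_PP + eng$k_bg
  x <- k * eng$H
  Ibar <- I0 * (if (x < 1e-8) 1 - x / 2 else (1 - exp(-x)) / x)

  ## (2) producer and bacterial growth with nutrient draw-down
  din <- no3 + nh4
  gross <- numeric(n)          # gross primary production, umol C
  ip <- eng$prod_idx
  if (length(ip)) {
    mu <- .producer_growth(eng$mu_max[ip], eng$K_N[ip], eng$K_P[ip],
                           eng$K_I[ip], Ibar, din, po4)
    gross[ip] <- mu * bio[ip] * dt
  }
  net_prod <- gross * (1 - EXUDATION_FRACTION)
  bact_g <- numeric(n)         # net bacterial biomass growth, umol C
  ib <- eng$bact_idx
  if (length(ib)) {
    mub <- .bacterial_growth(eng$mu_max[ib], eng$K_DOC[ib], eng$K_N[ib],
                             eng$K_P[ib], doc, din, po4)
    bact_g[ib] <- mub * bio[ib] * dt
  }
  # resource demands (dissolved units, mmol m^-3)
  doc_dem <- sum(bact_g[ib] / eng$gge[ib]) * UMOL_TO_MMOL
  s_doc <- if (doc_dem > 0) min(1, doc / doc_dem) else 1
  bact_g <- bact_g * s_doc     # provisional DOC limitation before N/P scaling
  n_dem <- (sum(net_prod) + sum(bact_g)) * REDFIELD_N_PER_C * UMOL_TO_MMOL
  p_dem <- (sum(net_prod) + sum(bact_g)) * REDFIELD_P_PER_C * UMOL_TO_MMOL
  s_n <- if (n_dem > 0) min(1, din / n_dem) else 1
  s_p <- if (p_dem > 0) min(1, po4 / p_dem) else 1
  s_np <- min(s_n, s_p)
  gross <- gross * s_np
  net_prod <- net_prod * s_np
  bact_g <- bact_g * s_np
  exud <- gross - net_prod
  doc_draw <- sum(bact_g / ifelse(eng$gge > 0, eng$gge, 1)) * UMOL_TO_MMOL
  growth_tot <- sum(net_prod) + sum(bact_g)
  n_draw <- growth_tot * REDFIELD_N_PER_C * UMOL_TO_MMOL
  p_draw <- growth_tot * REDFIELD_P_PER_C * UMOL_TO_MMOL
  d_nh4 <- min(nh4, n_draw)    # ammonium drawn preferentially
  d_no3 <- n_draw - d_nh4
  bio <- bio + net_prod + bact_g
  nh4 <- max(0, nh4 - d_nh4)
  no3 <- max(0, no3 - d_no3)
  po4 <- max(0, po4 - p_draw)
  doc <- max(0, doc - doc_draw) + sum(exud) * UMOL_TO_MMOL
  pp_C <- sum(gross)
  resp_C <- doc_draw / UMOL_TO_MMOL - sum(bact_g)  # bacterial respiration

  ## (3) grazing, flux-limited at the extinction floor of each prey
  Lmat <- eng$preyM * outer(eng$clearance, bio)
  Ltot <- rowSums(Lmat)
  si <- pmin(Ltot, eng$Imax)
  fac <- bio * ifelse(Ltot > 0, si / Ltot, 0) * dt
  ing <- fac * Lmat                       # rows: predators; cols: prey
  out <- colSums(ing)
  avail <- pmax(0, bio - eng$floor)
  sc <- ifelse(out > avail & out > 0, avail / out, 1)
  if (any(sc < 1)) {
    ing <- ing * rep(sc, each = n)
    out <- colSums(ing)
  }
  q <- ifelse(bio > 0, b1 / bio, 0)
  b1_leaving <- q * out                   # B1 removed with grazed prey
  Bin <- as.vector(ing %*% q)             # B1 in each predator's ration
  I_p <- rowSums(ing)
  bio <- bio - out
  b1 <- b1 - b1_leaving

  ## (4) ingestion partitioning and excretion
  growth_c <- ifelse(eng$fish, 0, eng$gge * I_p)
  doc_ex <- DOC_LOSS_FRACTION * (1 - eng$gge) * I_p
  resp_c <- (1 - eng$gge) * I_p - doc_ex + ifelse(eng$fish, eng$gge * I_p, 0)
  remin <- I_p - growth_c                 # carbon whose N, P return to pools
  bio <- bio + growth_c
  nh4 <- nh4 + sum(remin) * REDFIELD_N_PER_C * UMOL_TO_MMOL
  po4 <- po4 + sum(remin) * REDFIELD_P_PER_C * UMOL_TO_MMOL
  doc <- doc + sum(doc_ex) * UMOL_TO_MMOL
  resp_C <- resp_C + sum(resp_c)

  ## (4b) basal respiration: starving populations decline, remineralising
  ## N and P; limited at the extinction floor. B1 pools are not reduced
  ## here; any resulting quota excess is removed by the cap below.
  basal_loss <- pmin(eng$basal * bio * dt, pmax(0, bio - eng$floor))
  bio <- bio - basal_loss
  nh4 <- nh4 + sum(basal_loss) * REDFIELD_N_PER_C * UMOL_TO_MMOL
  po4 <- po4 + sum(basal_loss) * REDFIELD_P_PER_C * UMOL_TO_MMOL
  resp_C <- resp_C + sum(basal_loss)

  ## (5) vitamin B1: sources, transfer, turnover, quota caps
  src <- numeric(n)
  is_src <- c(eng$prod_idx, eng$bact_idx)
  if (length(is_src)) {
    qs <- ifelse(bio[is_src] > 0, b1[is_src] / bio[is_src], 0)
    s <- eng$metab[is_src] * eng$mult * (eng$qmax[is_src] - qs) *
      bio[is_src] * dt
    src[is_src] <- pmin(pmax(s, 0), eng$qmax[is_src] * bio[is_src] - b1[is_src])
  }
  b1 <- b1 + src
  turn <- ifelse(eng$cons, eng$metab * dt * b1, 0)
  absorbed <- eng$b * Bin
  b1 <- b1 - turn + absorbed
  cap <- eng$qmax * bio
  over <- pmax(0, b1 - cap)
  b1 <- b1 - over

  if (any(bio < 0) || any(b1 < 0) || no3 < 0 || nh4 < 0 || po4 < 0 ||
      doc < 0 || any(!is.finite(bio)) || any(!is.finite(b1)))
    stop("numerical failure: negative or non-finite pool after step; ",
         "pools = ", paste(signif(c(bio, b1, no3, nh4, po4, doc), 4),
                           collapse = " "))

  list(bio = bio, b1 = b1, no3 = no3, nh4 = nh4, po4 = po4, doc = doc,
       k = k, Ibar = Ibar, pp_C = pp_C, resp_C = resp_C, src = src,
       absorbed = absorbed, leaving = b1_leaving,
       deg_transfer = sum(Bin) - sum(absorbed), deg_turnover = sum(turn),
       overflow = sum(over))
}

#' Advance an ecosystem state by one time step
#'
#' Applies, in order: light forcing, producer/bacterial growth with nutrient
#' draw-down, grazing (bottom-up), ingestion partitioning and excretion, and
#' the vitamin B1 source/transfer/turnover/cap updates. Explicit Euler with
#' proportional flux limiting; there is no non-consumptive mortality.
#'
#' @param state List with named vectors `biomass` and `b1` (one entry per
#'   group), scalars `NO3`, `NH4`, `PO4`, `DOC`, and the current time `t`
#'   (days).
#' @param specs A `foodweb_specs` object.
#' @param forcing A [light_forcing()] object.
#' @param config A [sim_config()] object.
#' @param scenario A [scenario()] object.
#' @return The updated state (same shape, `t` advanced by `dt`).
#' @export
step_ecosystem <- function(state, specs, forcing, config, scenario) {
  eng <- build_engine(specs, scenario, config, forcing)
  I0 <- surface_irradiance(forcing, state$t + config$dt / 2)
  st <- .step_once(unname(state$biomass[eng$names]),
                   unname(state$b1[eng$names]),
                   state$NO3, state$NH4, state$PO4, state$DOC, I0, eng)
  list(biomass = stats::setNames(st$bio, eng$names),
       b1 = stats::setNames(st$b1, eng$names),
       NO3 = st$no3, NH4 = st$nh4, PO4 = st$po4, DOC = st$doc,
       t = state$t + config$dt)
}

init_state <- function(eng, scenario, config) {
  bio <- rep(max(config$seed_biomass, config$extinction_floor), eng$n)
  if (any(eng$fish))
    bio[eng$fish] <- eng$fish_abundance * eng$ind_mass[eng$fish]
  b1 <- config$initial_quota_fraction * eng$qmax * bio
  list(bio = bio, b1 = b1, no3 = scenario$NO3_0, nh4 = scenario$NH4_0,
       po4 = scenario$PO4_0, doc = config$initial_doc)
}

#' Run one scenario over the vegetative season
#'
#' Integrates the food web from season start to season end with daily
#' recording (pools at midnight, light as the daily mean) and a full
#' mass-balance ledger for C, N, P and B1. The model is deterministic:
#' identical inputs give identical outputs.
#'
#' @param scenario A [scenario()] object.
#' @param specs A `foodweb_specs` object (default [baltic_default_specs()]).
#' @param config A [sim_config()].
#' @param forcing A [light_forcing()].
#' @return An object of class `b1_sim`.
#' @export
run_scenario <- function(scenario, specs = baltic_default_specs(),
                         config = sim_config(), forcing = light_forcing()) {
  stopifnot(inherits(scenario, "scenario"))
  eng <- build_engine(specs, scenario, config, forcing)
  dt <- config$dt
  spd <- round(1 / dt)
  d0 <- config$season_start_day
  d1 <- config$season_end_day
  if ((d1 - d0) %% config$record_interval != 0)
    stop("record_interval must divide the season length")
  rec_days <- seq(d0, d1, by = config$record_interval)
  n_rec <- length(rec_days)
  n <- eng$n

  st <- init_state(eng, scenario, config)
  initial <- st

  biomass <- matrix(NA_real_, n_rec, n, dimnames = list(NULL, eng$names))
  quota <- biomass
  dissolved <- matrix(NA_real_, n_rec, 4,
                      dimnames = list(NULL, c("NO3", "NH4", "PO4", "DOC")))
  light <- matrix(NA_real_, n_rec, 2,
                  dimnames = list(NULL, c("mean_irradiance", "mean_k")))
  led <- list(pp_C = 0, resp_C = 0, b1_source = numeric(n),
              b1_absorbed = numeric(n), b1_leaving = numeric(n),
              b1_deg_transfer = 0, b1_deg_turnover = 0, b1_overflow = 0)

  record <- function(i, Imean, kmean) {
    biomass[i, ] <<- st$bio
    quota[i, ] <<- ifelse(st$bio > 0, st$b1 / st$bio, 0)
    dissolved[i, ] <<- c(st$no3, st$nh4, st$po4, st$doc)
    light[i, ] <<- c(Imean, kmean)
  }
  record(1, NA_real_, NA_real_)

  # all surface irradiances up front (forcing is state-independent)
  n_steps <- (d1 - d0) * spd
  I0_all <- surface_irradiance(forcing, d0 + (seq_len(n_steps) - 0.5) * dt)

  step_i <- 0L
  rec_i <- 1L
  steps_per_rec <- spd * config$record_interval
  for (blk in seq_len((n_rec - 1L))) {
    Iacc <- 0
    kacc <- 0
    for (s in seq_len(steps_per_rec)) {
      step_i <- step_i + 1L
      r <- .step_once(st$bio, st$b1, st$no3, st$nh4, st$po4, st$doc,
                      I0_all[step_i], eng)
      st$bio <- r$bio; st$b1 <- r$b1
      st$no3 <- r$no3; st$nh4 <- r$nh4; st$po4 <- r$po4; st$doc <- r$doc
      Iacc <- Iacc + r$Ibar
      kacc <- kacc + r$k
      led$pp_C <- led$pp_C + r$pp_C
      led$resp_C <- led$resp_C + r$resp_C
      led$b1_source <- led$b1_source + r$src
      led$b1_absorbed <- led$b1_absorbed + r$absorbed
      led$b1_leaving <- led$b1_leaving + r$leaving
      led$b1_deg_transfer <- led$b1_deg_transfer + r$deg_transfer
      led$b1_deg_turnover <- led$b1_deg_turnover + r$deg_turnover
      led$b1_overflow <- led$b1_overflow + r$overflow
    }
    rec_i <- rec_i + 1L
    record(rec_i, Iacc / steps_per_rec, kacc / steps_per_rec)
  }

  names(led$b1_source) <- names(led$b1_absorbed) <-
    names(led$b1_leaving) <- eng$names
  led$initial <- initial
  led$final <- st
  structure(list(days = rec_days, biomass = biomass, quota = quota,
                 dissolved = dissolved, light = light, ledger = led,
                 scenario = scenario, config = config, specs = specs,
                 forcing = forcing),
            class = "b1_sim")
}

#' Run a reduced food chain (test fixture)
#'
#' Runs the same engine on a minimal web of at most three groups, used for
#' analytic checking (nutrient-budget oracles, consumer lag, B1 ledger
#' bounds).
#'
#' @param chain_spec A `foodweb_specs` with at most 3 groups.
#' @param config A [sim_config()].
#' @param scenario A [scenario()] providing nutrients, `k_bg` and
#'   bioavailability.
#' @param forcing A [light_forcing()].
#' @return A `b1_sim` object.
#' @export
run_reduced_foodchain <- function(chain_spec, config = sim_config(),
                                  scenario = NULL,
                                  forcing = light_forcing()) {
  stopifnot(inherits(chain_spec, "foodweb_specs"))
  if (length(chain_spec) > 3)
    stop("reduced food chain must have at most 3 groups")
  if (is.null(scenario)) scenario <- scenario()
  run_scenario(scenario, specs = chain_spec, config = config,
               forcing = forcing)
}

#' Mass-balance residuals of a finished run
#'
#' Relative closure errors of the nitrogen, phosphorus, carbon and vitamin B1
#' budgets over the whole run, computed from the initial state, final state
#' and flux ledger.
#'
#' @param result A `b1_sim` object.
#' @return Named numeric vector with components `N`, `P`, `C`, `B1`.
#' @export
budget_residuals <- function(result) {
  stopifnot(inherits(result, "b1_sim"))
  led <- result$ledger
  tot_N <- function(s) s$no3 + s$nh4 +
    sum(s$bio) * REDFIELD_N_PER_C * UMOL_TO_MMOL
  tot_P <- function(s) s$po4 + sum(s$bio) * REDFIELD_P_PER_C * UMOL_TO_MMOL
  tot_C <- function(s) sum(s$bio) + s$doc / UMOL_TO_MMOL
  nN <- abs(tot_N(led$final) - tot_N(led$initial)) / tot_N(led$initial)
  nP <- abs(tot_P(led$final) - tot_P(led$initial)) / tot_P(led$initial)
  dC <- tot_C(led$final) - tot_C(led$initial)
  srcC <- led$pp_C - led$resp_C
  nC <- abs(dC - srcC) / max(abs(led$pp_C), 1e-12)
  dB1 <- sum(led$final$b1) - sum(led$initial$b1)
  srcB1 <- sum(led$b1_source) - led$b1_deg_transfer - led$b1_deg_turnover -
    led$b1_overflow
  nB1 <- abs(dB1 - srcB1) / max(sum(led$b1_source), 1e-300)
  c(N = nN, P = nP, C = nC, B1 = nB1)
}

#' @export
print.b1_sim <- function(x, ...) {
  cat("<b1_sim> scenario '", x$scenario$label, "': days ",
      min(x$days), "-", max(x$days), "\n", sep = "")
  cat("  fish abundance ", x$scenario$fish_abundance, " ind m^-3, N0 ",
      x$scenario$NO3_0 + x$scenario$NH4_0, " mmol m^-3, k_bg ",
      x$scenario$k_bg, " m^-1\n", sep = "")
  fin <- x$biomass[nrow(x$biomass), ]
  cat("  final biomass (umol C m^-3):\n")
  print(signif(fin, 3))
  res <- budget_residuals(x)
  cat("  budget residuals: ",
      paste(names(res), signif(res, 2), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.b1_sim <- function(object, rule = classification_rule(), ...) {
  out <- list(stats = summarize_run(object),
              classification = if ("fish" %in% colnames(object$quota))
                classify(object, rule) else NULL,
              residuals = budget_residuals(object))
  class(out) <- "summary.b1_sim"
  out
}

#' @export
print.summary.b1_sim <- function(x, ...) {
  if (!is.null(x$classification)) {
    cat("classification:", x$classification$label, "(fraction of days below",
        "threshold:", round(x$classification$fraction_days_below, 3), ")\n")
  }
  st <- x$stats
  cat("analysis-window statistics:\n")
  for (f in names(st)) cat(sprintf("  %-28s %.4g\n", f, st[[f]]))
  cat("budget residuals:",
      paste(names(x$residuals), signif(x$residuals, 2), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.b1_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  nb <- x$biomass
  nb[nb <= 0] <- NA
  graphics::matplot(x$days, nb, type = "l", log = "y", lty = 1,
                    xlab = "day of year", ylab = "biomass [umol C m^-3]",
                    ...)
  graphics::legend("bottomright", colnames(x$biomass), lty = 1,
                   col = seq_len(ncol(x$biomass)), cex = 0.6, bty = "n")
  if ("fish" %in% colnames(x$quota)) {
    graphics::plot(x$days, x$quota[, "fish"], type = "l",
                   xlab = "day of year", ylab = "fish B1 quota")
    graphics::abline(h = 6.41e-11, lty = 2)
  }
  invisible(x)
}

#' Tidy long-format view of a simulation
#'
#' @param x A `b1_sim` object.
#' @param ... Unused.
#' @return A data frame with columns `day`, `variable`, `group`, `value`.
#' @export
as.data.frame.b1_sim <- function(x, ...) {
  long <- function(mat, variable, groups = colnames(mat)) {
    data.frame(day = rep(x$days, times = ncol(mat)),
               variable = variable,
               group = rep(groups, each = nrow(mat)),
               value = as.vector(mat))
  }
  rbind(long(x$biomass, "biomass"),
        long(x$quota, "quota"),
        long(x$dissolved, "dissolved"),
        long(x$light, "light"))
}

#' Write / read a simulation result as tidy CSV
#'
#' @param result A `b1_sim` object.
#' @param path File path.
#' @return `write_result_csv` returns `path` invisibly; `read_result_csv`
#'   returns the tidy data frame.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
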
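#' Allometric scaling multiplier
#'
#' Power-law scaling `(volume / reference_volume)^exponent` used to derive
#' size-dependent rate constants: maximal growth rates of producers scale with
#' a negative exponent (small cells grow and take up nutrients faster per unit
#' carbon), while the light half-saturation scales with a positive exponent
#' (large cells absorb less light per unit volume and are therefore more
#' light-limited).
#'
#' @param volume Cell volume, um^3 (> 0).
#' @param reference_volume Reference cell volume, um^3 (> 0).
#' @param exponent Scaling exponent.
#' @return Dimensionless multiplier.
#' @export
allometric_scale <- function(volume, reference_volume, exponent) {
  if (any(volume <= 0) || any(reference_volume <= 0))
    stop("volumes must be > 0")
  (volume / reference_volume)^exponent
}

#' Static parameters of one trophic group
#'
#' @param name Group name.
#' @param role One of `"producer"`, `"heterotrophic_bacteria"`, `"consumer"`,
#'   `"fish"`.
#' @param volume Cell volume, um^3 (producers, bacteria, protozoa).
#' @param individual_mass Individual carbon mass, umol C per individual
#'   (fish only).
#' @param prey Character vector of prey group names (consumers and fish).
#' @param q_max Maximal vitamin B1 quota, umol B1 per umol C.
#' @param mu_max Maximal specific growth rate, d^-1 (producers, bacteria).
#' @param K_N,K_P Half-saturation for DIN and DIP, mmol m^-3.
#' @param K_DOC Half-saturation for DOC, mmol C m^-3 (bacteria).
#' @param K_I Light half-saturation, relative irradiance units (producers).
#' @param clearance Volume-specific clearance rate, m^3 (umol C)^-1 d^-1
#'   (consumers, fish).
#' @param I_max Maximal specific ingestion rate, d^-1 (consumers, fish).
#' @param gge Gross growth efficiency in (0, 1) (consumers, fish).
#' @param metabolic_rate Specific metabolic turnover, d^-1. Sets both the B1
#'   replenishment rate of producers/bacteria and the B1 turnover of all
#'   groups.
#' @param basal_respiration Specific basal carbon loss, d^-1 (default 0):
#'   biomass respired independently of feeding, with its N and P returned to
#'   the dissolved pools. Gives starving populations a decline rate; kept at
#'   zero for fish, whose population is constant.
#' @return An object of class `trophic_group_spec`.
#' @export
trophic_group_spec <- function(name, role,
                               volume = NA_real_, individual_mass = NA_real_,
                               prey = character(), q_max,
                               mu_max = NA_real_, K_N = NA_real_,
                               K_P = NA_real_, K_DOC = NA_real_,
                               K_I = NA_real_, clearance = NA_real_,
                               I_max = NA_real_, gge = NA_real_,
                               metabolic_rate, basal_respiration = 0) {
  roles <- c("producer", "heterotrophic_bacteria", "consumer", "fish")
  if (!role %in% roles)
    stop("unknown role '", role, "' for group '", name, "'")
  if (!is.numeric(q_max) || q_max <= 0) stop("q_max must be > 0")
  if (!is.numeric(metabolic_rate) || metabolic_rate < 0)
    stop("metabolic_rate must be >= 0")
  if (!is.numeric(basal_respiration) || basal_respiration < 0)
    stop("basal_respiration must be >= 0")
  if (role %in% c("producer", "heterotrophic_bacteria")) {
    if (is.na(mu_max) || mu_max < 0) stop("mu_max required and >= 0")
    if (length(prey) > 0) stop("producers/bacteria have no prey")
  }
  if (role %in% c("consumer", "fish")) {
    if (length(prey) < 1) stop("consumer '", name, "' needs a prey list")
    if (is.na(clearance) || clearance < 0) stop("clearance required and >= 0")
    if (is.na(I_max) || I_max < 0) stop("I_max required and >= 0")
    if (is.na(gge) || gge <= 0 || gge >= 1) stop("gge must be in (0, 1)")
  }
  if (role == "fish" && (is.na(individual_mass) || individual_mass <= 0))
    stop("fish need individual_mass > 0")
  structure(list(name = name, role = role, volume = volume,
                 individual_mass = individual_mass, prey = prey,
                 q_max = q_max, mu_max = mu_max, K_N = K_N, K_P = K_P,
                 K_DOC = K_DOC, K_I = K_I, clearance = clearance,
                 I_max = I_max, gge = gge, metabolic_rate = metabolic_rate,
                 basal_respiration = basal_respiration),
            class = "trophic_group_spec")
}

#' Assemble a food web from group specs
#'
#' Validates the wiring: every prey name must refer to a group in the web and
#' group names must be unique.
#'
#' @param ... `trophic_group_spec` objects.
#' @return A named list of specs with class `foodweb_specs`.
#' @export
foodweb_specs <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "trophic_group_spec"))
    specs <- specs[[1L]]
  ok <- vapply(specs, inherits, logical(1), "trophic_group_spec")
  if (!all(ok)) stop("all elements must be trophic_group_spec objects")
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate group names")
  names(specs) <- nm
  for (s in specs) {
    missing <- setdiff(s$prey, nm)
    if (length(missing))
      stop("group '", s$name, "' preys on unknown group(s): ",
           paste(missing, collapse = ", "))
  }
  structure(specs, class = "foodweb_specs")
}

#' @export
print.foodweb_specs <- function(x, ...) {
  cat("<foodweb_specs> with", length(x), "trophic groups\n")
  for (s in x) {
    prey <- if (length(s$prey)) paste0(" <- ", paste(s$prey, collapse = "+"))
            else ""
    cat(sprintf("  %-16s %-22s q_max %.3g%s\n", s$name, s$role, s$q_max, prey))
  }
  invisible(x)
}

#' Default Baltic-like food web parameterisation
#'
#' Eight trophic groups spanning heterotrophic bacteria, three size classes of
#' primary producers, two protozoan grazers, mesozooplankton and a small
#' planktivorous clupeid fish, wired so that each consumer feeds on the groups
#' one size class below it. Maximal B1 quotas are the empirically grounded
#' per-group values; rate constants follow allometric size scaling from a
#' 1 um^3 reference cell (growth exponent -0.1, light half-saturation
#' exponent +1/3, nutrient half-saturation exponent +0.1). All values can be
#' overridden via [apply_spec_overrides()] or the run configuration.
#'
#' @param overrides Optional named list of per-group parameter overrides, e.g.
#'   `list(picoalgae = list(mu_max = 1.5))`.
#' @return A `foodweb_specs` object.
#' @export
baltic_default_specs <- function(overrides = NULL) {
  mu_ref <- 2.0       # d^-1 at the 1 um^3 reference cell
  KI_ref <- 0.01      # relative irradiance units at reference volume
  KN_ref <- 0.3       # mmol N m^-3 at reference volume
  vol <- c(bacteria = 0.1, picoalgae = 1, nanoalgae = 1e2, microalgae = 1e4,
           nanoflagellates = 1e2, ciliates = 1e4)
  amu <- function(v) mu_ref * allometric_scale(v, 1, -0.1)
  aKI <- function(v) KI_ref * allometric_scale(v, 1, 1 / 3)
  aKN <- function(v) KN_ref * allometric_scale(v, 1, 0.1)
  prod <- function(name, v, q_max, metab, basal)
    trophic_group_spec(name, "producer", volume = v, q_max = q_max,
                       mu_max = amu(v), K_N = aKN(v), K_P = aKN(v) / 16,
                       K_I = aKI(v), metabolic_rate = metab,
                       basal_respiration = basal)
  cons <- function(name, v, prey, q_max, clearance, I_max, metab, basal)
    trophic_group_spec(name, "consumer", volume = v, prey = prey,
                       q_max = q_max, clearance = clearance, I_max = I_max,
                       gge = 0.3, metabolic_rate = metab,
                       basal_respiration = basal)
  specs <- foodweb_specs(
    trophic_group_spec("bacteria", "heterotrophic_bacteria",
                       volume = vol[["bacteria"]], q_max = 1.48e-7,
                       mu_max = 2.0, K_N = 0.3, K_P = 0.3 / 16, K_DOC = 5,
                       gge = 0.3, metabolic_rate = 1.0,
                       basal_respiration = 0.1),
    prod("picoalgae", vol[["picoalgae"]], 1.48e-7, 1.0, 0.05),
    prod("nanoalgae", vol[["nanoalgae"]], 1.18e-7, 0.5, 0.05),
    prod("microalgae", vol[["microalgae"]], 1.18e-7, 0.3, 0.05),
    cons("nanoflagellates", vol[["nanoflagellates"]],
         c("bacteria", "picoalgae"), 1.32e-7, 3e-4, 3.0, 0.3, 0.15),
    cons("ciliates", vol[["ciliates"]],
         c("nanoflagellates", "nanoalgae"), 1.27e-7, 2e-4, 2.0, 0.2, 0.1),
    cons("mesozooplankton", NA_real_,
         c("ciliates", "microalgae"), 1.28e-7, 2e-4, 0.8, 0.1, 0.02),
    trophic_group_spec("fish", "fish", individual_mass = 1.5e5,
                       prey = "mesozooplankton", q_max = 1.04e-10,
                       clearance = 1e-4, I_max = 0.05, gge = 0.3,
                       metabolic_rate = 0.03)
  )
  if (!is.null(overrides)) specs <- apply_spec_overrides(specs, overrides)
  specs
}

#' Override parameters of a food-web spec table
#'
#' @param specs A `foodweb_specs` object.
#' @param overrides Named list: `list(<group> = list(<param> = value, ...))`.
#' @return The modified `foodweb_specs`.
#' @export
apply_spec_overrides <- function(specs, overrides) {
  stopifnot(inherits(specs, "foodweb_specs"))
  if (is.null(overrides)) return(specs)
  if (!is.list(overrides) || is.null(names(overrides)))
    stop("`overrides` must be a named list keyed by group name")
  settable <- c("volume", "individual_mass", "prey", "q_max", "mu_max",
                "K_N", "K_P", "K_DOC", "K_I", "clearance", "I_max", "gge",
                "metabolic_rate", "basal_respiration")
  for (g in names(overrides)) {
    if (!g %in% names(specs)) stop("unknown group in overrides: '", g, "'")
    ov <- overrides[[g]]
    if (!is.list(ov) || is.null(names(ov)))
      stop("override for group '", g, "' must be a named list")
    bad <- setdiff(names(ov), settable)
    if (length(bad))
      stop("unknown parameter(s) for group '", g, "': ",
           paste(bad, collapse = ", "))
    for (p in names(ov)) specs[[g]][[p]] <- ov[[p]]
  }
  # re-validate wiring
  foodweb_specs(unclass(specs))
}
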
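## Instantaneous process rates. Exported functions validate their inputs; the
## simulation engine calls the same unvalidated kernels (prefixed with a dot)
## so the arithmetic has a single source of truth.

.monod <- function(conc, K) conc / (conc + K)

#' Monod nutrient limitation factor
#'
#' @param conc Resource concentration, mmol m^-3 (>= 0).
#' @param K Half-saturation concentration, mmol m^-3 (> 0).
#' @return Factor in `[0, 1)`: 0 at zero concentration, 0.5 at `conc == K`.
#' @export
nutrient_limitation <- function(conc, K) {
  if (any(conc < 0)) stop("`conc` must be >= 0")
  if (any(K <= 0)) stop("`K` must be > 0")
  .monod(conc, K)
}

.producer_growth <- function(mu_max, K_N, K_P, K_I, irradiance, DIN, DIP) {
  mu_max * pmin(.monod(DIN, K_N), .monod(DIP, K_P)) * .monod(irradiance, K_I)
}

#' Specific growth rate of a primary producer
#'
#' Liebig minimum of the Monod factors for DIN (`NO3 + NH4`) and DIP,
#' multiplied by a saturating light factor `I / (I + K_I)`.
#'
#' @param spec A `trophic_group_spec` with role `"producer"`.
#' @param mean_irradiance Depth-averaged irradiance (relative units).
#' @param DIN,DIP Dissolved inorganic N and P, mmol m^-3.
#' @return Specific growth rate, d^-1, in `[0, mu_max)`.
#' @export
producer_growth_rate <- function(spec, mean_irradiance, DIN, DIP) {
  stopifnot(inherits(spec, "trophic_group_spec"))
  if (spec$role != "producer")
    stop("`spec` must have role 'producer', got '", spec$role, "'")
  if (any(mean_irradiance < 0) || any(DIN < 0) || any(DIP < 0))
    stop("irradiance and nutrient concentrations must be >= 0")
  .producer_growth(spec$mu_max, spec$K_N, spec$K_P, spec$K_I,
                   mean_irradiance, DIN, DIP)
}

.bacterial_growth <- function(mu_max, K_DOC, K_N, K_P, DOC, DIN, DIP) {
  mu_max * pmin(.monod(DOC, K_DOC), .monod(DIN, K_N), .monod(DIP, K_P))
}

#' Specific growth rate of heterotrophic bacteria
#'
#' Liebig minimum over DOC (carbon substrate), DIN and DIP.
#'
#' @param spec A `trophic_group_spec` with role `"heterotrophic_bacteria"`.
#' @param DOC Dissolved organic carbon, mmol C m^-3.
#' @param DIN,DIP Dissolved inorganic N and P, mmol m^-3.
#' @return Specific growth rate, d^-1.
#' @export
bacterial_growth_rate <- function(spec, DOC, DIN, DIP) {
  stopifnot(inherits(spec, "trophic_group_spec"))
  if (spec$role != "heterotrophic_bacteria")
    stop("`spec` must have role 'heterotrophic_bacteria'")
  if (any(DOC < 0) || any(DIN < 0) || any(DIP < 0))
    stop("concentrations must be >= 0")
  .bacterial_growth(spec$mu_max, spec$K_DOC, spec$K_N, spec$K_P,
                    DOC, DIN, DIP)
}

# Per-prey ingestion fluxes [umol C m^-3 d^-1] for one predator.
# Clearance-rate (linear) feeding with total specific ingestion capped at
# I_max; the cap is shared across prey proportionally to clearance * prey.
.grazing <- function(clearance, I_max, pred_C, prey_C) {
  L <- clearance * prey_C
  Ltot <- sum(L)
  if (Ltot <= 0) return(rep(0, length(prey_C)))
  pred_C * min(Ltot, I_max) * (L / Ltot)
}

#' Grazing flux of a predator on its prey
#'
#' @param pred_spec A `trophic_group_spec` with role `"consumer"` or
#'   `"fish"`.
#' @param pred_biomass_C Predator carbon biomass, umol C m^-3.
#' @param prey_biomass_C Named or unnamed vector of prey carbon biomasses in
#'   the order of `pred_spec$prey`.
#' @return Vector of per-prey ingestion fluxes, umol C m^-3 d^-1.
#' @export
grazing_flux <- function(pred_spec, pred_biomass_C, prey_biomass_C) {
  stopifnot(inherits(pred_spec, "trophic_group_spec"))
  if (!pred_spec$role %in% c("consumer", "fish"))
    stop("`pred_spec` must be a consumer or fish")
  if (length(pred_spec$prey) == 0) stop("predator has an empty prey list")
  if (pred_biomass_C < 0 || any(prey_biomass_C < 0))
    stop("biomasses must be >= 0")
  if (length(prey_biomass_C) != length(pred_spec$prey))
    stop("`prey_biomass_C` must have one entry per prey")
  .grazing(pred_spec$clearance, pred_spec$I_max, pred_biomass_C,
           prey_biomass_C)
}

## Stoichiometric constants: Redfield C:N:P = 106:16:1 for all biomass.
## Biomass carbon is tracked in umol C m^-3, dissolved pools in mmol m^-3,
## hence the 1e-3 factor when moving N or P between biomass and solution.
REDFIELD_N_PER_C <- 16 / 106
REDFIELD_P_PER_C <- 1 / 106
UMOL_TO_MMOL <- 1e-3
MG_C_PER_UMOL <- 12.011e-3  # mg C per umol C

## Fraction of non-growth ingested carbon excreted as DOC (remainder is
## respired) and fraction of gross primary production exuded as DOC.
DOC_LOSS_FRACTION <- 0.2
EXUDATION_FRACTION <- 0.1

#' Partition ingested carbon into growth, respiration and excretion
#'
#' A fraction `gge` of ingested carbon becomes predator biomass; of the
#' remainder, 20% is excreted as DOC and 80% respired. All N and P of the
#' non-grown fraction returns to the NH4 and PO4 pools at Redfield
#' stoichiometry, so N and P are conserved exactly. For fish the grown carbon
#' is immediately remineralised as well (constant population size), while its
#' B1 content is retained.
#'
#' @param pred_spec A consumer or fish `trophic_group_spec`.
#' @param ingested_C Ingested carbon, umol C m^-3.
#' @return List with `growth_C`, `respired_C`, `excreted_DOC` (umol C m^-3)
#'   and `excreted_DIN`, `excreted_DIP` (mmol m^-3).
#' @export
partition_ingestion <- function(pred_spec, ingested_C) {
  stopifnot(inherits(pred_spec, "trophic_group_spec"))
  if (!pred_spec$role %in% c("consumer", "fish"))
    stop("`pred_spec` must be a consumer or fish")
  if (any(ingested_C < 0)) stop("`ingested_C` must be >= 0")
  gge <- pred_spec$gge
  growth <- gge * ingested_C
  losses <- ingested_C - growth
  doc <- DOC_LOSS_FRACTION * losses
  resp <- losses - doc
  if (pred_spec$role == "fish") {
    # constant population: somatic growth is remineralised immediately
    resp <- resp + growth
    n_back <- ingested_C * REDFIELD_N_PER_C * UMOL_TO_MMOL
    p_back <- ingested_C * REDFIELD_P_PER_C * UMOL_TO_MMOL
    growth <- 0
  } else {
    n_back <- losses * REDFIELD_N_PER_C * UMOL_TO_MMOL
    p_back <- losses * REDFIELD_P_PER_C * UMOL_TO_MMOL
  }
  list(growth_C = growth, respired_C = resp, excreted_DOC = doc,
       excreted_DIN = n_back, excreted_DIP = p_back)
}

#' Vitamin B1 source flux in producers and bacteria
#'
#' The cellular quota relaxes towards its maximum at a specific rate equal to
#' the group's metabolic rate times a global multiplier:
#' `flux = rate * (q_max - quota) * biomass_C`. The flux is zero at the quota
#' ceiling, so it can never push the quota above `q_max`.
#'
#' @param spec Producer or bacteria `trophic_group_spec`.
#' @param biomass_C Carbon biomass, umol C m^-3.
#' @param current_quota Current B1 quota, umol B1 per umol C.
#' @param b1_input_multiplier Global multiplier on the replenishment rate
#'   (default 1).
#' @return B1 gain, umol B1 m^-3 d^-1.
#' @export
b1_source_flux <- function(spec, biomass_C, current_quota,
                           b1_input_multiplier = 1) {
  stopifnot(inherits(spec, "trophic_group_spec"))
  if (!spec$role %in% c("producer", "heterotrophic_bacteria"))
    stop("consumers and fish gain B1 only by feeding")
  if (any(current_quota < 0) || any(current_quota > spec$q_max))
    stop("`current_quota` must lie in [0, q_max]")
  if (any(biomass_C < 0)) stop("`biomass_C` must be >= 0")
  spec$metabolic_rate * b1_input_multiplier *
    (spec$q_max - current_quota) * biomass_C
}

#' Bioavailability-discounted B1 transfer during grazing
#'
#' The B1 contained in ingested prey biomass is `prey_quota * ingested_C`; a
#' fraction `b` is absorbed by the consumer and the remainder is degraded.
#' Absorbed plus degraded equals exactly the B1 removed from the prey pool.
#'
#' @param ingested_C Ingested prey carbon, umol C m^-3.
#' @param prey_quota Prey B1 quota, umol B1 per umol C.
#' @param b Bioavailability in `[0, 1]`.
#' @return List with `absorbed_B1` and `degraded_B1`, umol B1 m^-3.
#' @export
b1_trophic_transfer <- function(ingested_C, prey_quota, b) {
  if (any(b < 0) || any(b > 1)) stop("`b` must lie in [0, 1]")
  if (any(ingested_C < 0) || any(prey_quota < 0))
    stop("`ingested_C` and `prey_quota` must be >= 0")
  total <- prey_quota * ingested_C
  list(absorbed_B1 = b * total, degraded_B1 = (1 - b) * total)
}

#' Update a consumer's B1 pool: turnover plus absorption
#'
#' First-order decay of the pool at the metabolic rate plus the absorbed
#' influx, then clipped so that the quota does not exceed `q_max` (any
#' overflow counts as degradation in the mass-balance ledger).
#'
#' @param spec Consumer or fish `trophic_group_spec`.
#' @param biomass_C_after_growth Biomass after this step's growth, umol C
#'   m^-3.
#' @param absorbed_B1 Absorbed B1 flux, umol B1 m^-3 d^-1.
#' @param old_pool Previous B1 pool, umol B1 m^-3.
#' @param dt Time step, d.
#' @return List with `pool` (new B1 pool) and `overflow` (B1 removed by the
#'   quota cap).
#' @export
b1_consumer_update <- function(spec, biomass_C_after_growth, absorbed_B1,
                               old_pool, dt = 1) {
  stopifnot(inherits(spec, "trophic_group_spec"))
  if (any(c(biomass_C_after_growth, absorbed_B1, old_pool, dt) < 0))
    stop("inputs must be >= 0")
  pool <- old_pool * (1 - spec$metabolic_rate * dt) + absorbed_B1 * dt
  cap <- spec$q_max * biomass_C_after_growth
  overflow <- max(0, pool - cap)
  list(pool = pool - overflow, overflow = overflow)
}

#' Update the fish B1 pool at constant population size
#'
#' Fish biomass is `abundance * individual_mass` and constant within a run;
#' the pool obeys the same turnover-plus-absorption update as other
#' consumers, so at a fixed total absorbed flux the equilibrium quota is
#' inversely proportional to abundance (dilution among individuals).
#'
#' @param spec Fish `trophic_group_spec`.
#' @param fish_abundance Individuals m^-3 (> 0).
#' @param absorbed_B1 Absorbed B1 flux, umol B1 m^-3 d^-1.
#' @param old_pool Previous B1 pool, umol B1 m^-3.
#' @param dt Time step, d.
#' @return List with `pool`, `quota` and `overflow`.
#' @export
b1_fish_update <- function(spec, fish_abundance, absorbed_B1, old_pool,
                           dt = 1) {
  stopifnot(inherits(spec, "trophic_group_spec"), spec$role == "fish")
  if (fish_abundance <= 0) stop("`fish_abundance` must be > 0")
  biomass <- fish_abundance * spec$individual_mass
  up <- b1_consumer_update(spec, biomass, absorbed_B1, old_pool, dt)
  list(pool = up$pool, quota = up$pool / biomass, overflow = up$overflow)
}
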
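# Shared fixtures, built in code.

# Short-season configuration for fast engine tests (10 simulated days).
short_config <- function(dt = 0.02, days = 10, ...) {
  sim_config(dt = dt, season_start_day = 89, season_end_day = 89 + days,
             analysis_start_day = 89 + max(1, days %/% 2), ...)
}

# Reference scenarios used by the robustness checks: one from the B1-rich
# interior (low fish, mid nutrients, clear water) and one from the B1-poor
# corner (high fish, very high nutrients, intermediate attenuation).
ref_rich_scenario <- function(...)
  scenario(fish_abundance = 0.004, NO3_0 = 16.005, NH4_0 = 3.965,
           k_bg = 0.04, label = "ref_rich", ...)
ref_poor_scenario <- function(...)
  scenario(fish_abundance = 0.01, NO3_0 = 30, NH4_0 = 7,
           k_bg = 0.14, label = "ref_poor", ...)

# Total dissolved + biomass-bound nitrogen / phosphorus of a state list as
# stored in the ledger (umol C biomass at Redfield 106:16:1; dissolved in
# mmol m^-3).
total_N <- function(state)
  state$no3 + state$nh4 + sum(state$bio) * (16 / 106) * 1e-3
total_P <- function(state)
  state$po4 + sum(state$bio) * (1 / 106) * 1e-3
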
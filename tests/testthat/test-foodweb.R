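specs <- baltic_default_specs()

test_that("default web carries the empirical maximal B1 quotas and wiring", {
  qmax <- vapply(specs, `[[`, numeric(1), "q_max")
  expect_equal(unname(qmax[c("bacteria", "picoalgae", "nanoalgae",
                             "microalgae", "nanoflagellates", "ciliates",
                             "mesozooplankton", "fish")]),
               c(1.48e-7, 1.48e-7, 1.18e-7, 1.18e-7, 1.32e-7, 1.27e-7,
                 1.28e-7, 1.04e-10))
  expect_setequal(specs$nanoflagellates$prey, c("bacteria", "picoalgae"))
  expect_setequal(specs$ciliates$prey, c("nanoflagellates", "nanoalgae"))
  expect_setequal(specs$mesozooplankton$prey, c("ciliates", "microalgae"))
  expect_equal(specs$fish$prey, "mesozooplankton")
  gge <- vapply(specs[c("nanoflagellates", "ciliates", "mesozooplankton",
                        "fish")], `[[`, numeric(1), "gge")
  expect_true(all(gge > 0 & gge < 1))
})

test_that("spec constructors validate roles, prey and overrides", {
  expect_error(trophic_group_spec("x", "plant", q_max = 1,
                                  metabolic_rate = 1), "role")
  expect_error(trophic_group_spec("x", "consumer", q_max = 1,
                                  metabolic_rate = 1), "prey")
  expect_error(foodweb_specs(trophic_group_spec(
    "lonely", "consumer", prey = "ghost", q_max = 1, clearance = 1,
    I_max = 1, gge = 0.3, metabolic_rate = 1)), "unknown group")
  ov <- apply_spec_overrides(specs, list(picoalgae = list(mu_max = 1.23)))
  expect_equal(ov$picoalgae$mu_max, 1.23)
  expect_error(apply_spec_overrides(specs, list(krill = list(mu_max = 1))),
               "unknown group")
  expect_error(apply_spec_overrides(specs, list(picoalgae = list(zap = 1))),
               "unknown parameter")
})

test_that("Monod limitation has its defining anchor points", {
  expect_equal(nutrient_limitation(0, 1), 0)
  expect_equal(nutrient_limitation(2, 2), 0.5)
  expect_equal(nutrient_limitation(3, 1), 0.75)
  expect_error(nutrient_limitation(-1, 1))
  expect_error(nutrient_limitation(1, 0))
})

test_that("allometric scaling is a power law with identity anchors", {
  expect_equal(allometric_scale(7, 7, -0.25), 1)
  expect_equal(allometric_scale(16, 1, -0.25), 0.5)
  expect_equal(allometric_scale(1e6, 1, 0), 1)
  expect_error(allometric_scale(0, 1, 1))
})

test_that("producer growth is Liebig-limited times a light factor", {
  p <- trophic_group_spec("p", "producer", volume = 1, q_max = 1e-7,
                          mu_max = 1.0, K_N = 1, K_P = 1, K_I = 1,
                          metabolic_rate = 1)
  expect_equal(producer_growth_rate(p, 0, 10, 10), 0)
  expect_equal(producer_growth_rate(p, 100, 0, 100), 0)
  # f_N = 0.8, f_P = 0.5, f_I = 0.5 -> min(0.8, 0.5) * 0.5 = 0.25
  expect_equal(producer_growth_rate(p, 1, 4, 1), 0.25)
  expect_error(producer_growth_rate(specs$bacteria, 1, 1, 1), "producer")
})

test_that("bacterial growth is the Liebig minimum over DOC, N and P", {
  b <- trophic_group_spec("b", "heterotrophic_bacteria", volume = 0.1,
                          q_max = 1e-7, mu_max = 2, K_N = 1, K_P = 1,
                          K_DOC = 1, metabolic_rate = 1)
  expect_equal(bacterial_growth_rate(b, 0, 10, 10), 0)
  expect_equal(bacterial_growth_rate(b, 1e12, 1e12, 1e12), 2,
               tolerance = 1e-9)
  # f_DOC = 0.6, f_N = 0.9, f_P = 0.8 -> 2 * 0.6 = 1.2
  expect_equal(bacterial_growth_rate(b, 1.5, 9, 4), 1.2)
  expect_error(bacterial_growth_rate(specs$picoalgae, 1, 1, 1))
})

test_that("grazing is linear in prey at low density and caps at I_max", {
  nf <- specs$nanoflagellates
  # linear regime: clearance * prey << I_max
  prey <- c(bacteria = 2, picoalgae = 3)
  fl <- grazing_flux(nf, 10, prey)
  expect_equal(fl, nf$clearance * prey * 10, tolerance = 1e-12)
  expect_equal(grazing_flux(nf, 10, c(0, 0)), c(0, 0))
  # saturation: specific ingestion -> I_max exactly
  huge <- c(1e12, 1e12)
  expect_equal(sum(grazing_flux(nf, 10, huge)) / 10, nf$I_max)
  # the cap is shared proportionally to clearance * prey
  fl2 <- grazing_flux(nf, 1, c(3e12, 1e12))
  expect_equal(fl2[1] / fl2[2], 3)
  expect_error(grazing_flux(specs$picoalgae, 1, 1), "consumer")
})

test_that("ingestion partitioning follows the gge/DOC split and conserves N", {
  ms <- specs$mesozooplankton  # gge = 0.3
  p <- partition_ingestion(ms, 100)
  expect_equal(p$growth_C, 30)
  expect_equal(p$excreted_DOC, 14)   # 0.2 * 70
  expect_equal(p$respired_C, 56)
  # N conservation: ingested N = growth N + excreted DIN
  rN <- 16 / 106 * 1e-3
  expect_equal(100 * rN, p$growth_C * rN + p$excreted_DIN, tolerance = 1e-15)
  z <- partition_ingestion(ms, 0)
  expect_true(all(unlist(z) == 0))
  # fish remineralise their somatic growth but carbon still balances
  pf <- partition_ingestion(specs$fish, 100)
  expect_equal(pf$growth_C, 0)
  expect_equal(pf$respired_C + pf$excreted_DOC, 100)
  expect_equal(pf$excreted_DIN, 100 * rN, tolerance = 1e-15)
})

test_that("B1 source flux relaxes the quota towards q_max", {
  pico <- specs$picoalgae
  expect_equal(b1_source_flux(pico, 100, pico$q_max), 0)
  # full deficit at unit rate and unit biomass: one q_max per day
  p1 <- trophic_group_spec("p", "producer", volume = 1, q_max = 2e-7,
                           mu_max = 1, K_N = 1, K_P = 1, K_I = 1,
                           metabolic_rate = 1)
  expect_equal(b1_source_flux(p1, 1, 0), 2e-7)
  # linear in the source multiplier
  f1 <- b1_source_flux(pico, 50, 0.3 * pico$q_max, 1)
  expect_equal(b1_source_flux(pico, 50, 0.3 * pico$q_max, 0.1), 0.1 * f1)
  expect_equal(b1_source_flux(pico, 50, 0.3 * pico$q_max, 10), 10 * f1)
  expect_error(b1_source_flux(specs$fish, 1, 0), "feeding")
})

test_that("trophic B1 transfer splits by bioavailability and balances", {
  tr <- b1_trophic_transfer(1000, 1.28e-7, 0.15)
  expect_equal(tr$absorbed_B1, 1.92e-5)
  expect_equal(tr$degraded_B1, 1.088e-4)
  expect_equal(tr$absorbed_B1 + tr$degraded_B1, 1.28e-7 * 1000)
  expect_equal(b1_trophic_transfer(10, 1e-7, 0)$absorbed_B1, 0)
  expect_equal(b1_trophic_transfer(10, 1e-7, 1)$degraded_B1, 0)
  expect_error(b1_trophic_transfer(10, 1e-7, 1.2), "\\[0, 1\\]")
})

test_that("consumer B1 pool decays at the metabolic rate and caps at q_max", {
  ms <- trophic_group_spec("m", "consumer", prey = "x", q_max = 1e-6,
                           clearance = 1, I_max = 1, gge = 0.3,
                           metabolic_rate = 0.1)
  up <- b1_consumer_update(ms, 1e9, 0, 10, dt = 1)
  expect_equal(up$pool, 9)
  expect_equal(up$overflow, 0)
  # absorption beyond the cap overflows into the ledger
  up2 <- b1_consumer_update(ms, 1, 10, 0, dt = 1)
  expect_equal(up2$pool, 1e-6)
  expect_equal(up2$overflow, 10 - 1e-6)
  ms0 <- trophic_group_spec("m", "consumer", prey = "x", q_max = 1e-6,
                            clearance = 1, I_max = 1, gge = 0.3,
                            metabolic_rate = 0)
  expect_equal(b1_consumer_update(ms0, 1e9, 0, 5, 1)$pool, 5)
})

test_that("fish quota dilutes with abundance and never exceeds its q_max", {
  fish <- specs$fish
  # steady state pool = absorbed / turnover; quota inversely prop. abundance
  steady_quota <- function(ab) {
    pool <- 0
    for (i in 1:4000) {
      up <- b1_fish_update(fish, ab, absorbed_B1 = 1e-9, old_pool = pool,
                           dt = 0.02)
      pool <- up$pool
    }
    up$quota
  }
  q1 <- steady_quota(0.004)
  q2 <- steady_quota(0.008)
  expect_equal(q1 / q2, 2, tolerance = 1e-3)
  # without absorption the quota decays monotonically to zero
  pool <- 1e-7; last <- Inf
  for (i in 1:50) {
    up <- b1_fish_update(fish, 0.004, 0, pool, dt = 1)
    expect_lt(up$quota, last)
    last <- up$quota; pool <- up$pool
  }
  # cap at the empirical fish maximum
  up <- b1_fish_update(fish, 0.004, absorbed_B1 = 1, old_pool = 0, dt = 1)
  expect_equal(up$quota, 1.04e-10)
  expect_error(b1_fish_update(fish, 0, 0, 0), "abundance")
})
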
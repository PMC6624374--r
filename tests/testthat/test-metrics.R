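test_that("classification counts below-threshold days with strict bounds", {
  rule <- classification_rule()
  days <- 152:274
  n <- length(days)
  # constant series above threshold: rich
  cl <- classify_series(days, rep(1e-10, n), rule)
  expect_equal(cl$fraction_days_below, 0)
  expect_equal(cl$label, "b1_rich")
  # constructed series with 40% of window days below: poor
  fx <- fixture_quota_series(n, 0.40, start_day = 152)
  cl40 <- classify_series(fx$day, fx$fish_quota, rule)
  expect_equal(cl40$fraction_days_below, round(0.40 * n) / n)
  expect_equal(cl40$label, "b1_poor")
  # exactly 30% below: strict inequality -> intermediate
  q <- rep(1e-10, 100)
  q[1:30] <- 1e-11
  cl30 <- classify_series(152:251, q, rule, window_start = 152,
                          window_end = 251)
  expect_equal(cl30$fraction_days_below, 0.30)
  expect_equal(cl30$label, "intermediate")
  # all below: poor
  clall <- classify_series(days, rep(0, n), rule)
  expect_equal(clall$label, "b1_poor")
  expect_error(classify_series(200:274, rep(0, 75), rule), "window")
})

test_that("classification depends only on the fish quota series", {
  r <- run_scenario(scenario(), config = short_config(days = 20))
  cl1 <- classify(r)
  r2 <- r
  r2$biomass <- r2$biomass * 100         # rescale non-fish outputs
  r2$quota[, colnames(r2$quota) != "fish"] <- 0
  expect_equal(classify(r2)$fraction_days_below, cl1$fraction_days_below)
  expect_equal(classify(r2)$label, cl1$label)
})

test_that("summary statistics match hand arithmetic", {
  r <- run_scenario(scenario(), config = short_config(days = 6))
  # overwrite the analysis window with constructed series
  w <- which(r$days >= r$config$analysis_start_day)
  n <- length(w)
  expect_equal(n %% 2, 0)  # window length even by construction of the config
  r$biomass[w, "mesozooplankton"] <- 2
  st <- summarize_run(r)
  expect_equal(st$mean_mesozoo_biomass, 2)
  expect_equal(st$cv_mesozoo, 0)
  # series alternating 1, 3: mean 2, population sd 1, CV 0.5
  r$biomass[w, "ciliates"] <- rep(c(1, 3), length.out = n)
  expect_equal(summarize_run(r)$cv_ciliates, 0.5)
  # equal producer biomasses -> picoalgae fraction 1/3
  r$biomass[w, c("picoalgae", "nanoalgae", "microalgae")] <- 7
  st3 <- summarize_run(r)
  expect_equal(st3$picoalgae_biomass_fraction, 1 / 3)
  # zero-mean series gives the undefined sentinel, not infinity
  r$biomass[w, "microalgae"] <- 0
  expect_true(is.na(summarize_run(r)$cv_microalgae))
})

test_that("decay chain reproduces the trophic attenuation arithmetic", {
  # one consumer level at 15% bioavailability: 1/0.15 = 6.67-fold
  expect_equal(decay_chain(0.15, 1)$fold_reduction, 1 / 0.15)
  # four levels: ~0.5 permille survives, ~2000-fold reduction
  d4 <- decay_chain(0.15, 4)
  expect_equal(d4$surviving_fraction, 0.15^4)
  expect_equal(d4$fold_reduction, 0.15^-4)
  # two levels: ~2%
  expect_equal(decay_chain(0.15, 2)$surviving_fraction, 0.0225)
  # identity at zero levels; sentinel at zero bioavailability
  expect_equal(decay_chain(0.5, 0)$surviving_fraction, 1)
  expect_true(is.na(decay_chain(0, 3)$fold_reduction))
  expect_error(decay_chain(1.5, 1))
  expect_error(decay_chain(0.5, 2.5))
})

test_that("decay chain composes as a semigroup and is monotone in n", {
  set.seed(3)
  for (i in 1:20) {
    b <- runif(1, 0.01, 1)
    m <- sample(0:5, 1); n <- sample(0:5, 1)
    expect_equal(decay_chain(b, m + n)$surviving_fraction,
                 decay_chain(b, m)$surviving_fraction *
                   decay_chain(b, n)$surviving_fraction,
                 tolerance = 1e-12)
  }
  surv <- vapply(0:6, function(n) decay_chain(0.3, n)$surviving_fraction,
                 numeric(1))
  expect_true(all(diff(surv) < 0))
})

test_that("consumer-level map places picoalgae four levels below fish", {
  expect_equal(consumer_levels_to_fish("picoalgae"), 4)
  expect_equal(consumer_levels_to_fish("microalgae"), 2)
  expect_equal(consumer_levels_to_fish("bacteria"), 4)
  expect_error(consumer_levels_to_fish("fish"))
})

test_that("cube report keys rows by scenario and flags pico dominance", {
  grid <- scenario_grid(2, 2, 2)
  man <- grid_manifest(grid)
  mk_cl <- function(frac) structure(
    list(fraction_days_below = frac,
         label = if (frac > 0.3) "b1_poor" else "b1_rich",
         window_start = 152, window_end = 274, n_days = 123),
    class = "scenario_classification")
  mk_sm <- function(pf) {
    s <- list(mean_mesozoo_biomass = 1, cv_ciliates = 1, cv_microalgae = 1,
              cv_picoalgae = 1, cv_mesozoo = 1,
              picoalgae_biomass_fraction = pf, median_depth_avg_light = 0.1,
              median_DIN = 1, median_DIP = 0.1)
    class(s) <- c("summary_stats", "list")
    s
  }
  cls <- lapply(seq_len(8) / 10, mk_cl)
  sms <- lapply(seq_len(8) / 10, mk_sm)
  rep <- cube_report(cls, sms, man)
  expect_equal(nrow(rep), 8)
  expect_equal(sum(rep$label_class == "b1_poor"), 5)
  expect_equal(sum(rep$pico_fraction_above_median), 4)
  # duplicate ids rejected
  man2 <- man; man2$label[2] <- man2$label[1]
  expect_error(cube_report(cls, sms, man2), "duplicate")
  # empty input gives an empty table
  empty <- cube_report(list(), list(), man[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("fish B1 intake respects the analytic decay-chain bound", {
  # zero out every B1 source except picoalgae so all absorbed B1 provably
  # originated there, then compare the ledger to the analytic bound b^4
  # (turnover only adds losses, so realised transfer must be smaller)
  tiny <- 1e-30
  specs <- baltic_default_specs(overrides = list(
    bacteria = list(q_max = tiny),
    nanoalgae = list(q_max = tiny),
    microalgae = list(q_max = tiny)))
  scn <- scenario(fish_abundance = 0.004, NO3_0 = 16.005, NH4_0 = 3.965,
                  k_bg = 0.04)
  r <- run_scenario(scn, specs = specs,
                    config = sim_config(initial_quota_fraction = 0))
  led <- r$ledger
  b <- scn$bioavailability
  # direct link: fish absorb at most b times the B1 leaving mesozooplankton
  expect_lte(led$b1_absorbed[["fish"]],
             b * led$b1_leaving[["mesozooplankton"]] * (1 + 1e-9))
  # end-to-end: picoalgae -> fish efficiency below the b^n chain limit
  produced <- sum(led$b1_source)
  expect_gt(produced, 0)
  expect_lt(led$b1_absorbed[["fish"]] / produced,
            decay_chain(b, 4)$surviving_fraction)
})
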
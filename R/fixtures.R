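#' Synthetic daily fish-quota series (test support)
#'
#' Deterministic series with exactly `round(fraction_below * n_days)` days
#' strictly below the threshold. Below-threshold days sit at half the
#' threshold, the remainder at 1.5 times the threshold; below days are
#' spread evenly through the series.
#'
#' @param n_days Number of days (>= 1).
#' @param fraction_below Target fraction of below-threshold days in
#'   `[0, 1]`.
#' @param threshold Quota threshold, umol B1 per umol C.
#' @param start_day Day of year of the first value (default 152, the
#'   analysis window start).
#' @return Data frame with columns `day` and `fish_quota`.
#' @export
fixture_quota_series <- function(n_days, fraction_below,
                                 threshold = 6.41e-11, start_day = 152) {
  if (n_days < 1 || n_days != round(n_days)) stop("`n_days` must be >= 1")
  if (fraction_below < 0 || fraction_below > 1)
    stop("`fraction_below` must lie in [0, 1]")
  n_below <- round(fraction_below * n_days)
  quota <- rep(1.5 * threshold, n_days)
  if (n_below > 0) {
    pos <- unique(floor(seq(1, n_days, length.out = n_below)))
    # seq guarantees n_below distinct positions when n_below <= n_days
    pos <- pos[seq_len(min(n_below, length(pos)))]
    if (length(pos) < n_below)
      pos <- seq_len(n_below)
    quota[pos] <- 0.5 * threshold
  }
  data.frame(day = start_day + seq_len(n_days) - 1L, fish_quota = quota)
}

#' Toy reduced food-chain specs (test support)
#'
#' Small webs for analytic checking: a single producer, a producer-grazer
#' pair, or a producer-grazer-carnivore chain, all drawn from the default
#' parameterisation.
#'
#' @param type `"producer"`, `"producer_grazer"` or `"chain3"`.
#' @return A `foodweb_specs` with 1-3 groups.
#' @export
fixture_chain_specs <- function(type = c("producer", "producer_grazer",
                                         "chain3")) {
  type <- match.arg(type)
  base <- baltic_default_specs()
  pico <- base$picoalgae
  nf <- base$nanoflagellates
  nf$prey <- "picoalgae"
  cil <- base$ciliates
  cil$prey <- "nanoflagellates"
  switch(type,
         producer = foodweb_specs(pico),
         producer_grazer = foodweb_specs(pico, nf),
         chain3 = foodweb_specs(pico, nf, cil))
}
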
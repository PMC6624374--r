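#' Seasonal and diel light forcing
#'
#' Describes surface irradiance at a mid-latitude site as a truncated solar
#' elevation model: solar declination gives the annual cycle, the hour angle
#' gives the day-night cycle, and the result is normalised so that noon at the
#' summer solstice equals `peak_noon_irradiance`. Irradiance is in relative
#' units; only the shape matters because light limitation of growth is a
#' saturating factor.
#'
#' @param latitude Degrees north. Default 56.93 (Baltic proper).
#' @param peak_noon_irradiance Irradiance at summer-solstice noon (relative
#'   units, default 1).
#' @return An object of class `light_forcing`.
#' @export
light_forcing <- function(latitude = 56.93, peak_noon_irradiance = 1.0) {
  if (!is.numeric(latitude) || length(latitude) != 1L || abs(latitude) >= 90)
    stop("`latitude` must be a single number strictly between -90 and 90")
  if (!is.numeric(peak_noon_irradiance) || peak_noon_irradiance < 0)
    stop("`peak_noon_irradiance` must be non-negative")
  structure(list(latitude = latitude,
                 peak_noon_irradiance = peak_noon_irradiance),
            class = "light_forcing")
}

#' @export
print.light_forcing <- function(x, ...) {
  cat("<light_forcing> latitude", x$latitude, "degN, peak noon irradiance",
      x$peak_noon_irradiance, "\n")
  invisible(x)
}

# Solar declination [rad] for a given (continuous) day of year.
solar_declination <- function(day) {
  -23.44 * pi / 180 * cos(2 * pi * (day + 10) / 365)
}

#' Surface irradiance at a point in time
#'
#' Time is continuous days since 1 January, 00:00 local solar time, so `t =
#' 171.5` is noon on day 171. The declination is held fixed within each
#' calendar day, which makes the diel course exactly symmetric about solar
#' noon. Negative solar elevations are truncated to zero (night).
#'
#' @param forcing A [light_forcing()] object.
#' @param t Time in days (vectorised).
#' @return Non-negative irradiance in the same relative units as
#'   `peak_noon_irradiance`.
#' @export
surface_irradiance <- function(forcing, t) {
  stopifnot(inherits(forcing, "light_forcing"))
  day <- floor(t)
  hour <- (t - day) * 24
  lat <- forcing$latitude * pi / 180
  decl <- solar_declination(day)
  ha <- pi / 12 * (hour - 12)
  s <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  # noon at summer solstice (declination at the obliquity maximum)
  s_peak <- sin(lat) * sin(23.44 * pi / 180) + cos(lat) * cos(23.44 * pi / 180)
  forcing$peak_noon_irradiance * pmax(0, s) / s_peak
}

#' Light attenuation model
#'
#' Attenuation in the mixed layer is the sum of algal self-shading,
#' proportional to total algal carbon, and a background term from dissolved
#' organic and inorganic substances: `k = k_s * W_PP + k_bg`.
#'
#' @param k_s Self-shading coefficient, m^2 per mg algal C. Default 5e-5, so a
#'   dense bloom of ~2000 mg C m^-3 adds ~0.1 m^-1, comparable to the
#'   background range.
#' @param k_bg Background attenuation, m^-1 (must be > 0).
#' @param layer_depth Mixed-layer depth H in m (default 10).
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(k_s = 5e-5, k_bg = 0.14, layer_depth = 10) {
  if (!is.numeric(k_s) || k_s < 0) stop("`k_s` must be >= 0")
  if (!is.numeric(k_bg) || k_bg <= 0) stop("`k_bg` must be > 0")
  if (!is.numeric(layer_depth) || layer_depth <= 0)
    stop("`layer_depth` must be > 0")
  structure(list(k_s = k_s, k_bg = k_bg, layer_depth = layer_depth),
            class = "attenuation_model")
}

#' Total attenuation coefficient
#'
#' @param model An [attenuation_model()].
#' @param W_PP Total algal carbon biomass, mg C m^-3 (vectorised).
#' @return k in m^-1; always >= `k_bg`.
#' @export
attenuation_coefficient <- function(model, W_PP) {
  stopifnot(inherits(model, "attenuation_model"))
  if (any(W_PP < 0)) stop("`W_PP` must be >= 0")
  model$k_s * W_PP + model$k_bg
}

#' Depth-averaged irradiance in a mixed layer
#'
#' Vertical average of the Lambert-Beer profile `I0 * exp(-k z)` over
#' `z in [0, H]`, i.e. `I0 * (1 - exp(-k H)) / (k H)`. A series branch is used
#' for very small optical depth to avoid cancellation.
#'
#' @param I0 Surface irradiance (>= 0, vectorised).
#' @param k Attenuation coefficient, m^-1 (> 0).
#' @param H Layer depth, m (> 0).
#' @return Mean irradiance over the layer; lies in (0, I0] for I0 > 0.
#' @export
depth_averaged_irradiance <- function(I0, k, H) {
  if (any(I0 < 0)) stop("`I0` must be >= 0")
  if (any(k <= 0)) stop("`k` must be > 0")
  if (any(H <= 0)) stop("`H` must be > 0")
  x <- k * H
  f <- ifelse(x < 1e-8, 1 - x / 2, (1 - exp(-x)) / x)
  I0 * f
}
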
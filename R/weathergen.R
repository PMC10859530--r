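#' Generate one synthetic weather season
#'
#' Draws a 365-day daily weather series (calendar dates on a non-leap
#' reference year) from a water-deficit archetype. Rain occurrence follows
#' the archetype's monthly Markov chain, wet-day amounts are gamma
#' distributed with the calibrated mean, temperature follows a seasonal sine
#' with AR(1)-free daily noise, and radiation follows a clear-sky seasonal
#' curve attenuated on wet days. The caller's RNG state is untouched: the
#' stream is derived from `(seed, year_index)` only, so identical arguments
#' give bit-identical series.
#'
#' @param archetype an [archetype()] object.
#' @param year_index integer year number within a simulated site (>= 1).
#' @param seed integer master seed.
#' @return a `data.frame` of class `lt_weather` with columns `date`, `doy`,
#'   `tmax`, `tmin`, `radn` (MJ m-2 d-1) and `rain` (mm), 365 rows.
#' @examples
#' w <- generate_season(archetype("WW"), year_index = 1, seed = 42)
#' sum(w$rain[w$doy >= 121 & w$doy <= 304])
#' @export
generate_season <- function(archetype, year_index = 1L, seed = 1L) {
  validate_archetype(archetype)
  a <- archetype
  m <- month_of_doy()
  with_seed(derive_seed(seed, 1001L, year_index), {
    # occurrence chain, started from the January stationary distribution
    wet <- logical(365)
    pw <- a$p01[1] / (1 + a$p01[1] - a$p11[1])
    prev <- stats::runif(1) < pw
    u <- stats::runif(365)
    for (d in 1:365) {
      p <- if (prev) a$p11[m[d]] else a$p01[m[d]]
      wet[d] <- u[d] < p
      prev <- wet[d]
    }
    nwet <- sum(wet)
    rain <- numeric(365)
    if (nwet > 0) {
      rain[wet] <- stats::rgamma(nwet, shape = a$rain_shape,
                                 scale = a$rain_scale / a$rain_shape)
    }
    doy <- 1:365
    tmean <- a$tmean_annual + a$tamp * cos(2 * pi * (doy - 197) / 365) +
      stats::rnorm(365, sd = a$noise_sd)
    half_range <- a$diurnal_range / 2 * ifelse(wet, 0.8, 1) # clouds damp range
    tmax <- tmean + half_range
    tmin <- tmean - half_range
    clear <- 17.5 + 10 * cos(2 * pi * (doy - 172) / 365)
    radn <- clear * ifelse(wet, a$wet_attenuation, 1)
    out <- data.frame(
      date = as.Date(doy - 1, origin = "2001-01-01"),
      doy = doy, tmax = tmax, tmin = tmin, radn = radn, rain = rain
    )
    attr(out, "archetype") <- a$name
    attr(out, "year_index") <- as.integer(year_index)
    class(out) <- c("lt_weather", "data.frame")
    out
  })
}

#' Growing-season (May-October) precipitation total of a series
#'
#' @param weather an `lt_weather` data frame.
#' @return total rain in mm over day-of-year 121-304.
#' @export
season_rain <- function(weather) {
  sum(weather$rain[weather$doy >= SEASON_START_DOY &
                   weather$doy <= SEASON_END_DOY])
}

#' Synthetic east-to-west site gradient
#'
#' Builds `n_sites` site specifications reproducing the structure of the US
#' sorghum belt gradient: going west, precipitation declines and vapour
#' pressure deficit rises, so the archetype mixture shifts from WW/LD-
#' dominated to MD/ED-dominated, recommended plant density falls from 14 to
#' 6 plants m-2, and soils shift from heavier to lighter textures. Site 1 is
#' the easternmost. The construction is deterministic; the mixtures are the
#' per-year sampling frequencies of each archetype at the site.
#'
#' @param n_sites number of sites (>= 2).
#' @param seed integer; retained for interface symmetry (construction itself
#'   is deterministic).
#' @return a `data.frame` with one row per site: `site`, mixture weights
#'   `w_WW`, `w_LD`, `w_MD`, `w_ED` (rows sum to 1), `density`
#'   (plants m-2), `texture` and `depth_cm`.
#' @export
generate_gradient_sites <- function(n_sites, seed = 1L) {
  if (n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  g <- seq(0, 1, length.out = n_sites) # 0 = east, 1 = west
  east <- c(WW = 0.55, LD = 0.30, MD = 0.10, ED = 0.05)
  west <- c(WW = 0.05, LD = 0.15, MD = 0.35, ED = 0.45)
  w <- t(vapply(g, function(x) (1 - x) * east + x * west, numeric(4)))
  textures <- c("silty clay loam", "silty clay loam", "loam", "loam",
                "sandy loam")
  tex <- textures[pmin(5, 1 + floor(g * 4.999))]
  data.frame(
    site = seq_len(n_sites),
    w_WW = w[, 1], w_LD = w[, 2], w_MD = w[, 3], w_ED = w[, 4],
    density = round(14 - 8 * g),
    texture = tex,
    depth_cm = ifelse(g > 0.75, 150, 200)
  )
}

#' Draw the archetype sequence for a site's years
#'
#' Samples one archetype per year from the site's mixture weights, seeded.
#'
#' @param site one row of [generate_gradient_sites()].
#' @param n_years number of years.
#' @param seed master seed.
#' @return character vector of archetype names, length `n_years`.
#' @export
draw_site_archetypes <- function(site, n_years, seed = 1L) {
  w <- as.numeric(site[c("w_WW", "w_LD", "w_MD", "w_ED")])
  stopifnot(abs(sum(w) - 1) < 1e-8)
  with_seed(derive_seed(seed, 2001L, site$site),
            sample(c("WW", "LD", "MD", "ED"), n_years, replace = TRUE,
                   prob = w))
}
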
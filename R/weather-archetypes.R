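#' Seasonal water-deficit weather archetypes
#'
#' The generator describes each recurring water-deficit pattern of the US
#' sorghum belt as an *archetype*: a first-order two-state Markov chain of
#' wet/dry days with monthly transition probabilities (`p01` = P(wet | dry),
#' `p11` = P(wet | wet)), gamma-distributed wet-day rain amounts, a seasonal
#' sine temperature model and a clear-sky radiation curve attenuated on wet
#' days. Four archetypes are shipped:
#'
#' \describe{
#'   \item{WW}{well-watered or light stress at grain filling; mean May-October
#'     precipitation 400 mm.}
#'   \item{LD}{late drought: wet-day probabilities suppressed over the last
#'     ~40\% of the growing season (September-October); 300 mm.}
#'   \item{MD}{mid-season drought: suppression over ~30-70\% of the season
#'     (July-August); 244 mm.}
#'   \item{ED}{early drought: suppression before ~45\% of the season
#'     (May-July); 230 mm.}
#' }
#'
#' The gamma intensity mean of each archetype is solved in closed form from
#' the chain's exact daily wet-probability recursion so that the *expected*
#' May-October total equals the archetype's target; drier archetypes carry a
#' hotter mean and a wider diurnal temperature range, which raises their
#' vapour pressure deficit.
#'
#' @param name one of `"WW"`, `"LD"`, `"MD"`, `"ED"`.
#' @return an object of class `lt_archetype`: a list with monthly `p01`,
#'   `p11` (length 12), `rain_shape`, `rain_scale` (mm), temperature
#'   parameters (`tmean_annual`, `tamp`, `diurnal_range`, `noise_sd`, all
#'   deg C), `wet_attenuation`, and `target_rain_mm`.
#' @examples
#' a <- archetype("ED")
#' a$target_rain_mm
#' @export
archetype <- function(name = c("WW", "LD", "MD", "ED")) {
  name <- match.arg(name)
  # baseline monthly wet-day transition probabilities (continental semiarid,
  # frequent convective events in summer)
  p01 <- pmin(0.95, c(0.10, 0.10, 0.15, 0.20, 0.26, 0.26, 0.26, 0.23, 0.19,
                      0.15, 0.10, 0.10) * 1.4)
  p11 <- pmin(0.95, c(0.35, 0.35, 0.40, 0.45, 0.52, 0.52, 0.52, 0.48, 0.42,
                      0.40, 0.35, 0.35) * 1.15)
  # Dry-spell windows multiply p01 strongly and p11 moderately; wet windows
  # raise occurrence (more frequent, smaller events after calibration),
  # which is what keeps a regime well watered. Windows sit in
  # *crop-development* time for a May-sown crop flowering in early July:
  # an early drought needs a dry spring (it must also deplete the fallow
  # storage) and typically breaks with midsummer rains; a mid-season
  # "flash" drought follows a wet spring and spans flowering (July-August);
  # a late drought dries out the grain-filling months (August-October).
  sup <- function(m, f01 = 0.03, f11 = 0.15) {
    p01[m] <<- p01[m] * f01
    p11[m] <<- p11[m] * f11
  }
  wet <- function(m, f = 1.6, g = 1.25) {
    p01[m] <<- pmin(0.95, p01[m] * f)
    p11[m] <<- pmin(0.95, p11[m] * g)
  }
  switch(name,
    WW = { wet(5:8); wet(9:10, 2.0, 1.5) },
    LD = { wet(5:7); sup(8:10) },
    MD = { wet(5:6); sup(7:8) },
    ED = { sup(3:6); wet(7:10, 2.2, 1.5) }
  )
  target <- switch(name, WW = 400, LD = 300, MD = 244, ED = 230)
  out <- structure(list(
    name = name,
    p01 = p01, p11 = p11,
    rain_shape = 1.5,
    rain_scale = 1,                 # placeholder, calibrated below
    tmean_annual = switch(name, WW = 12.5, LD = 13.0, MD = 13.5, ED = 14.0),
    tamp = switch(name, WW = 13.0, LD = 13.5, MD = 14.0, ED = 14.0),
    diurnal_range = switch(name, WW = 9.0, LD = 12.5, MD = 14.0, ED = 15.5),
    noise_sd = 2.0,
    wet_attenuation = 0.75,
    target_rain_mm = target
  ), class = "lt_archetype")
  validate_archetype(out)
  # calibrate intensity so E[May-Oct rain] = target
  ewet <- sum(daily_wet_probability(out)[SEASON_START_DOY:SEASON_END_DOY])
  out$rain_scale <- target / ewet
  out
}

validate_archetype <- function(a) {
  if (!all(is.finite(c(a$p01, a$p11))) ||
      length(a$p01) != 12L || length(a$p11) != 12L ||
      any(a$p01 < 0 | a$p01 > 1) || any(a$p11 < 0 | a$p11 > 1)) {
    stop("invalid archetype: monthly p01/p11 must be 12 probabilities in [0,1]",
         call. = FALSE)
  }
  invisible(a)
}

# month index for each day of a 365-day year
month_of_doy <- function() {
  rep.int(1:12, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
}

#' Exact daily wet-day probability of an archetype's Markov chain
#'
#' Iterates the two-state chain's marginal probability day by day through the
#' monthly transition schedule, starting from the January stationary
#' distribution. Used for closed-form calibration of the rain intensity.
#'
#' @param a an `lt_archetype`.
#' @return numeric vector of length 365.
#' @export
daily_wet_probability <- function(a) {
  m <- month_of_doy()
  p <- numeric(365)
  pw <- a$p01[1] / (1 + a$p01[1] - a$p11[1]) # January stationary wet prob.
  for (d in 1:365) {
    pw <- pw * a$p11[m[d]] + (1 - pw) * a$p01[m[d]]
    p[d] <- pw
  }
  p
}

#' Expected May-October precipitation of an archetype
#'
#' @param a an `lt_archetype`.
#' @return expected growing-season total, mm.
#' @export
expected_season_rain <- function(a) {
  sum(daily_wet_probability(a)[SEASON_START_DOY:SEASON_END_DOY]) * a$rain_scale
}
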
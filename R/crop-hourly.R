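#' Daily thermal time (broken-stick cardinal response)
#'
#' Thermal time accrues on the daily mean temperature with cardinal
#' temperatures Tbase/Topt/Tceil: zero at or below Tbase, rising linearly to
#' a maximum of (Topt - Tbase) degree-days at Topt, falling linearly back to
#' zero at Tceil. Defaults 11/30/42 deg C are the usual sorghum cardinal
#' set.
#'
#' @param tmax,tmin daily extremes, deg C (tmax >= tmin).
#' @param tbase,topt,tceil cardinal temperatures, deg C.
#' @return thermal time, deg C d.
#' @examples
#' daily_thermal_time(30, 20) # 14 degree-days
#' @export
daily_thermal_time <- function(tmax, tmin, tbase = 11, topt = 30, tceil = 42) {
  stopifnot(all(tmax >= tmin))
  tm <- (tmax + tmin) / 2
  tt <- ifelse(tm <= tbase | tm >= tceil, 0,
        ifelse(tm <= topt, tm - tbase,
               (topt - tbase) * (tceil - tm) / (tceil - topt)))
  pmax(0, tt)
}

#' Hourly air temperature from daily extremes
#'
#' A single-cosine diurnal curve with its maximum at 14:00 and minimum
#' before dawn; the vector's maximum equals tmax and minimum equals tmin
#' exactly.
#'
#' @param tmax,tmin daily extremes, deg C.
#' @return numeric vector of 24 hourly temperatures (hours 0..23).
#' @export
hourly_temperature <- function(tmax, tmin) {
  stopifnot(tmax >= tmin)
  h <- 0:23
  (tmax + tmin) / 2 + (tmax - tmin) / 2 * cos(2 * pi * (h - 14) / 24)
}

#' Saturation vapour pressure (Tetens)
#'
#' es(T) = 0.6108 exp(17.27 T / (T + 237.3)), kPa.
#' @param temp air temperature, deg C.
#' @export
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

#' Hourly vapour pressure deficit
#'
#' Hourly temperatures come from [hourly_temperature()]; the dewpoint is
#' taken equal to tmin (the standard assumption when humidity is not
#' observed), so `vpd_h = max(0, es(T_h) - es(tmin))`.
#'
#' @param tmax,tmin daily extremes, deg C.
#' @return numeric vector of 24 hourly VPD values, kPa.
#' @examples
#' max(hourly_vpd(30, 15)) # about 2.54 kPa at 14:00
#' @export
hourly_vpd <- function(tmax, tmin) {
  th <- hourly_temperature(tmax, tmin)
  pmax(0, svp(th) - svp(tmin))
}

#' Hourly shares of daily solar radiation
#'
#' A half-sine over the daylight window centred on solar noon; shares sum
#' to 1, nighttime shares are 0.
#'
#' @param daylength daylight duration, hours.
#' @return numeric vector of 24 shares.
#' @export
hourly_radiation_share <- function(daylength = 12) {
  h <- 0:23 + 0.5
  rise <- 12 - daylength / 2
  s <- sin(pi * (h - rise) / daylength)
  s[h < rise | h > 12 + daylength / 2] <- 0
  s <- pmax(0, s)
  s / sum(s)
}

#' Light-limited daily biomass increment
#'
#' rue x radn x (1 - exp(-k LAI)), g m-2.
#'
#' @param radn daily solar radiation, MJ m-2.
#' @param lai leaf area index.
#' @param rue radiation use efficiency, g MJ-1.
#' @param k canopy light extinction coefficient.
#' @export
light_limited_biomass <- function(radn, lai, rue = 1.25, k = 0.5) {
  stopifnot(radn >= 0, lai >= 0)
  rue * radn * (1 - exp(-k * lai))
}

#' Hourly transpiration demand
#'
#' Each daylight hour's share of the potential (light-limited) biomass is
#' converted to water demand through the transpiration-efficiency relation:
#' `demand_h = pot_biomass * share_h * vpd_h / te_coeff` with the TE
#' coefficient in Pa, yielding mm of water (1 mm = 1000 g m-2).
#'
#' @param potential_biomass light-limited biomass increment, g m-2.
#' @param radn_share 24-vector of hourly radiation shares (sums to 1).
#' @param vpd_hourly 24-vector of hourly VPD, kPa.
#' @param te_coeff transpiration-efficiency coefficient, Pa.
#' @return 24-vector of hourly demand, mm h-1.
#' @export
hourly_demand <- function(potential_biomass, radn_share, vpd_hourly,
                          te_coeff = 9) {
  stopifnot(potential_biomass >= 0, te_coeff > 0)
  potential_biomass * radn_share * vpd_hourly / te_coeff
}

#' Apply the limited-transpiration hourly cap
#'
#' The LT trait is a flat ceiling on hourly transpiration demand:
#' elementwise `min(demand_h, cap)`. An infinite cap (non-LT phenotype)
#' returns the demand unchanged.
#'
#' @param demand_hourly 24-vector of hourly demand, mm h-1.
#' @param transp_cap hourly cap, mm h-1 (0.2-0.9 for LT phenotypes, `Inf`
#'   for non-LT).
#' @return capped 24-vector.
#' @examples
#' apply_lt_cap(c(0.2, 0.5, 1.2, 0.8), 0.9) # total 2.4 instead of 2.7
#' @export
apply_lt_cap <- function(demand_hourly, transp_cap = Inf) {
  stopifnot(transp_cap > 0)
  pmin(demand_hourly, transp_cap)
}

#' Water-limited growth from hourly supply and demand
#'
#' The day's stress index is `waterSD = min(1, supply / sum(capped demand))`
#' (1 when there is no demand). Actual hourly transpiration is the capped
#' demand scaled by waterSD, and the biomass increment converts water back
#' through the TE relation hour by hour:
#' `dB = sum(transp_h * te_coeff / vpd_h)` over hours with positive VPD.
#' With no demand the day is water-unlimited (`dbiomass = Inf` is returned
#' and the caller takes the light-limited value).
#'
#' @param capped_demand 24-vector after [apply_lt_cap()], mm h-1.
#' @param supply potential root water supply today, mm.
#' @param vpd_hourly 24-vector of hourly VPD, kPa.
#' @param te_coeff transpiration-efficiency coefficient, Pa.
#' @return list with `dbiomass` (g m-2), `transpiration` (mm),
#'   `transp_hourly` (24-vector, mm) and `waterSD` in [0, 1].
#' @export
water_limited_growth <- function(capped_demand, supply, vpd_hourly,
                                 te_coeff = 9) {
  stopifnot(supply >= 0)
  total_demand <- sum(capped_demand)
  if (total_demand <= 0) {
    return(list(dbiomass = Inf, transpiration = 0,
                transp_hourly = numeric(24), waterSD = 1))
  }
  watersd <- min(1, supply / total_demand)
  transp <- capped_demand * watersd
  pos <- vpd_hourly > 0
  db <- sum(transp[pos] * te_coeff / vpd_hourly[pos])
  list(dbiomass = db, transpiration = sum(transp), transp_hourly = transp,
       waterSD = watersd)
}
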
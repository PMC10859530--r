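#' Partition daily rain into runoff and infiltration
#'
#' A threshold-excess rule: no runoff below the profile's daily threshold;
#' above it a fixed fraction of the excess runs off. Conservation
#' (runoff + infiltration = rain) holds exactly and runoff is monotone
#' non-decreasing in rain.
#'
#' @param soil an `lt_soil` profile (supplies threshold and fraction).
#' @param rain daily rain, mm (>= 0).
#' @return list with `runoff` and `infiltration` (mm).
#' @export
partition_rain <- function(soil, rain) {
  stopifnot(rain >= 0)
  runoff <- attr(soil, "runoff_frac") *
    max(0, rain - attr(soil, "runoff_threshold_mm"))
  list(runoff = runoff, infiltration = rain - runoff)
}

#' Tipping-bucket drainage cascade
#'
#' Processes layers top-down: water above SAT cascades to the layer below
#' immediately; water above DUL drains downward at the profile's drainage
#' coefficient. Excess leaving the bottom layer is deep drainage.
#' Optionally adds infiltration to the surface layer first.
#'
#' @param soil an `lt_soil` profile.
#' @param infiltration water entering the surface layer today, mm.
#' @return list with the updated `soil` and `drainage` (mm lost below the
#'   profile).
#' @export
drain_cascade <- function(soil, infiltration = 0) {
  stopifnot(infiltration >= 0)
  th <- soil$thickness_mm
  swmm <- soil$sw * th
  flow <- infiltration
  coef <- attr(soil, "drain_coef")
  for (i in seq_len(nrow(soil))) {
    swmm[i] <- swmm[i] + flow
    satmm <- soil$sat[i] * th[i]
    dulmm <- soil$dul[i] * th[i]
    over_sat <- max(0, swmm[i] - satmm)
    swmm[i] <- swmm[i] - over_sat
    drain <- coef * max(0, swmm[i] - dulmm)
    swmm[i] <- swmm[i] - drain
    flow <- over_sat + drain
  }
  soil$sw <- swmm / th
  list(soil = soil, drainage = flow)
}

#' Daily soil evaporation (two-stage, surface layer only)
#'
#' Potential evaporation is an energy-limited term (0.4 mm per MJ m-2 of
#' radiation) shaded by the canopy through exp(-k_e LAI). Stage I applies
#' while cumulative evaporation since the last wetting is below the U limit;
#' afterwards stage II falls off with the square root of time. Evaporation
#' never takes the surface layer below its air-dry limit (half of LL15).
#'
#' @param soil an `lt_soil` profile (carries the `evap_cum` memory).
#' @param radn daily solar radiation, MJ m-2.
#' @param lai canopy leaf area index.
#' @param ke canopy extinction coefficient for soil shading.
#' @return list with updated `soil` and `evaporation` (mm).
#' @export
soil_evaporation <- function(soil, radn, lai = 0, ke = 0.5) {
  u <- attr(soil, "evap_u_mm")
  cona <- attr(soil, "evap_cona")
  cum <- attr(soil, "evap_cum")
  epot <- 0.4 * radn * exp(-ke * lai)
  if (cum < u) {
    rate <- min(epot, u - cum) # finish stage I, energy-limited
  } else {
    t2 <- (cum - u) / cona     # equivalent stage-II days already elapsed
    rate <- min(epot, cona * (sqrt(t2 + 1) - sqrt(t2)))
  }
  air_dry <- 0.5 * soil$ll15[1]
  avail <- max(0, (soil$sw[1] - air_dry) * soil$thickness_mm[1])
  rate <- min(rate, avail)
  soil$sw[1] <- soil$sw[1] - rate / soil$thickness_mm[1]
  attr(soil, "evap_cum") <- cum + rate
  list(soil = soil, evaporation = rate)
}

# wetting partially resets the evaporation memory (rain refills stage I)
note_wetting <- function(soil, infiltration) {
  attr(soil, "evap_cum") <- max(0, attr(soil, "evap_cum") - infiltration)
  soil
}

# per-layer potential extraction (mm) for a given root depth
layer_supply <- function(soil, root_depth) {
  top <- cumsum(soil$thickness_mm) - soil$thickness_mm
  rooted <- pmax(0, pmin(soil$thickness_mm, root_depth - top)) /
    soil$thickness_mm
  soil$kl * pmax(0, soil$sw - soil$ll15) * soil$thickness_mm * rooted
}

#' Potential daily root water supply
#'
#' The kl convention: each rooted layer can yield `kl (sw - ll15) thickness`
#' mm per day, the deepest partially-rooted layer pro-rata by the rooted
#' fraction.
#'
#' @param soil an `lt_soil` profile.
#' @param root_depth rooting front depth, mm.
#' @return supply, mm d-1.
#' @export
potential_supply <- function(soil, root_depth) {
  stopifnot(root_depth >= 0)
  sum(layer_supply(soil, root_depth))
}

#' Extract transpired water from the rooted profile
#'
#' Uptake is apportioned across rooted layers proportionally to their
#' layer-wise potential supply. `demand_actual` must not exceed the
#' profile's potential supply.
#'
#' @param soil an `lt_soil` profile.
#' @param demand_actual transpiration to extract, mm.
#' @param root_depth rooting front depth, mm.
#' @return updated profile.
#' @export
extract_transpiration <- function(soil, demand_actual, root_depth) {
  if (demand_actual < 0) stop("demand must be >= 0", call. = FALSE)
  ls <- layer_supply(soil, root_depth)
  tot <- sum(ls)
  if (demand_actual > tot + 1e-9) {
    stop(sprintf("transpiration demand (%.6f mm) exceeds supply (%.6f mm)",
                 demand_actual, tot), call. = FALSE)
  }
  if (demand_actual > 0 && tot > 0) {
    uptake <- ls / tot * demand_actual
    soil$sw <- soil$sw - uptake / soil$thickness_mm
  }
  soil
}

#' Check water-balance closure of a season flux ledger
#'
#' For a daily ledger with columns `rain`, `runoff`, `drainage`,
#' `evaporation`, `transpiration` and `dstorage`, returns the largest
#' absolute daily residual of
#' rain - runoff - drainage - evaporation - transpiration - dstorage.
#'
#' @param ledger a data frame as produced by [run_season()]'s `$ledger`.
#' @return maximum absolute residual, mm.
#' @export
water_balance_closure <- function(ledger) {
  res <- with(ledger,
              rain - runoff - drainage - evaporation - transpiration - dstorage)
  max(abs(res))
}
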
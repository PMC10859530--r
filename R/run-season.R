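#' Simulate one crop season
#'
#' Runs the daily coupled soil-crop loop over one weather year: a fallow
#' water balance from 1 January to sowing (so the sowing-day profile
#' reflects winter/spring rain on top of the 1 January initial moisture),
#' then the crop loop — thermal-time phenology, TPLA leaf area,
#' light-limited biomass, hourly VPD and transpiration demand, the LT
#' hourly cap, root water supply, water-limited growth, per-layer uptake and
#' grain set/filling — until physiological maturity or the end of the
#' weather series.
#'
#' A season *fails* when flowering is not reached (either the series ends
#' first, or the crop dies once the canopy is established and the 14-day
#' running mean of `waterSD` falls below 0.1 before flowering); failed
#' seasons carry `NA` yield.
#'
#' @param weather a validated daily weather series covering the year
#'   (>= 365 rows).
#' @param soil an `lt_soil` profile from [make_soil()].
#' @param cultivar an [cultivar()] object.
#' @param management a [management()] object.
#' @return an object of class `lt_season`: a list with `daily` (one row per
#'   crop day: phase, lai, dbiomass, biomass, transpiration, waterSD,
#'   plant-available water, cumulative thermal time), `ledger` (full-period
#'   daily water fluxes), hourly VPD/transpiration matrices, and summary
#'   fields (anthesis and maturity day-of-year, grain number, `dry_yield`
#'   and `yield` at 12.5\% moisture in Mg ha-1, `total_transpiration`,
#'   biomass/transpiration/soil water at flowering, `failed`).
#' @examples
#' w <- generate_season(archetype("WW"), 1, seed = 7)
#' s <- run_season(w, make_soil("loam", 200), cultivar("short"), management())
#' s$yield
#' @export
run_season <- function(weather, soil, cultivar, management) {
  weather <- validate_weather(weather)
  cv <- cultivar
  mg <- management
  if (nrow(weather) < 365) {
    stop("weather series shorter than a full season (need >= 365 days)",
         call. = FALSE)
  }
  sow_doy <- as.integer(format(
    as.Date(paste0(format(weather$date[1], "%Y"), "-", mg$sowing_date)),
    "%j"))
  soil <- initialize_moisture(soil, mg$initial_fasw)
  profile_depth <- sum(soil$thickness_mm)
  n <- nrow(weather)

  led <- data.frame(doy = weather$doy, rain = weather$rain, runoff = 0,
                    drainage = 0, evaporation = 0, transpiration = 0,
                    dstorage = 0)
  # crop state
  sown <- FALSE; cum_tt <- 0; phase <- 0L
  root_depth <- 0; lai <- 0
  biomass <- 0; b_fi_sgf <- 0; days_fi_sgf <- 0L
  grain_n_m2 <- NA_real_; grain_mass <- 0; reserve <- 0
  reached_gf <- FALSE
  anthesis <- NA_integer_; maturity <- NA_integer_
  biomass_fl <- NA_real_; transp_fl <- NA_real_; pasw_fl <- NA_real_
  lai_fl <- NULL
  crop_transp <- 0; wsd_recent <- numeric(0); stress_kill <- FALSE
  # preallocated daily-record columns (filled for crop days only)
  r_used <- logical(n)
  r_phase <- character(n); r_tt <- r_cumtt <- r_lai <- r_db <- r_bio <-
    r_tr <- r_wsd <- r_pasw <- numeric(n)
  vpd_mat <- matrix(0, n, 24); tr_mat <- matrix(0, n, 24)

  for (d in seq_len(n)) {
    doy <- weather$doy[d]
    w0 <- profile_water(soil)
    pr <- partition_rain(soil, weather$rain[d])
    soil <- note_wetting(soil, pr$infiltration)
    dc <- drain_cascade(soil, pr$infiltration)
    soil <- dc$soil

    if (!sown && doy == sow_doy) {
      sown <- TRUE
      root_depth <- mg$sowing_depth_mm
    }

    transp_today <- 0; watersd <- 1; db <- 0; tt <- 0
    vpd_h <- numeric(24); tr_h <- numeric(24)
    if (sown && is.na(maturity) && !stress_kill) {
      tt <- daily_thermal_time(weather$tmax[d], weather$tmin[d],
                               cv$tbase, cv$topt, cv$tceil)
      cum_tt <- cum_tt + tt
      dl <- daylength_hours(doy, mg$latitude)
      ph <- advance_phenology(cum_tt, cv, dl)
      phase <- ph$phase
      ext <- cv$photoperiod_slope * max(0, dl - cv$pp_threshold)
      tg <- phase_targets(cv, ext)

      if (phase >= 1 && is.na(anthesis)) {
        root_depth <- min(profile_depth, root_depth + 30)
      }
      tt_em <- cum_tt - tg[["emergence"]]
      tt_fl <- max(0, cum_tt - tg[["flowering"]])
      lai <- if (phase >= 2) {
        leaf_area(tt_em, cv, mg$density, tt_fl, lai_fl)
      } else 0

      if (phase >= 2) {
        pot <- light_limited_biomass(weather$radn[d], lai, cv$rue, cv$k)
        vpd_h <- hourly_vpd(weather$tmax[d], weather$tmin[d])
        shares <- hourly_radiation_share(dl)
        dem <- hourly_demand(pot, shares, vpd_h, cv$te_coeff)
        capped <- apply_lt_cap(dem, cv$transp_cap)
        supply <- potential_supply(soil, root_depth)
        wlg <- water_limited_growth(capped, supply, vpd_h, cv$te_coeff)
        db <- min(pot, wlg$dbiomass)
        transp_today <- wlg$transpiration
        watersd <- wlg$waterSD
        tr_h <- wlg$transp_hourly
        soil <- extract_transpiration(soil, transp_today, root_depth)
        crop_transp <- crop_transp + transp_today
      }

      # grain set and filling
      if (phase >= 4 && phase <= 6) {
        b_fi_sgf <- b_fi_sgf + db
        days_fi_sgf <- days_fi_sgf + 1L
      }
      if (phase >= 7 && !reached_gf) {
        reached_gf <- TRUE
        gn_plant <- grain_number(b_fi_sgf / mg$density,
                                 max(1L, days_fi_sgf), cv$dm_per_seed)
        grain_n_m2 <- gn_plant * mg$density
        reserve <- cv$stem_reserve_frac * 0.5 * biomass
      }
      biomass <- biomass + db
      if (phase == 7L) {
        pot_grain <- cv$grain_fill_rate_mg * grain_n_m2 / 1000
        gain <- min(pot_grain, db + reserve)
        reserve <- reserve - max(0, gain - db)
        grain_mass <- grain_mass + gain
      }

      if (phase >= 6 && is.na(anthesis)) {
        anthesis <- doy
        biomass_fl <- biomass
        transp_fl <- crop_transp
        pasw_fl <- plant_available_water(soil)
        lai_fl <- lai
      }
      if (phase >= 9 && is.na(maturity)) maturity <- doy

      # pre-flowering terminal stress: crop dies when the 14-day mean
      # stress index stays near total stress before flowering
      if (phase >= 3 && phase < 6) {
        wsd_recent <- c(wsd_recent, watersd)
        nr <- length(wsd_recent)
        if (nr >= 14L && mean(wsd_recent[(nr - 13L):nr]) < 0.1) {
          stress_kill <- TRUE
        }
      }

      r_used[d] <- TRUE
      r_phase[d] <- if (phase == 0) "sown" else PHASES[phase]
      r_tt[d] <- tt; r_cumtt[d] <- cum_tt; r_lai[d] <- lai
      r_db[d] <- db; r_bio[d] <- biomass; r_tr[d] <- transp_today
      r_wsd[d] <- watersd; r_pasw[d] <- plant_available_water(soil)
      vpd_mat[d, ] <- vpd_h; tr_mat[d, ] <- tr_h
    }

    ev <- soil_evaporation(soil, weather$radn[d], lai)
    soil <- ev$soil
    w1 <- profile_water(soil)
    led$runoff[d] <- pr$runoff
    led$drainage[d] <- dc$drainage
    led$evaporation[d] <- ev$evaporation
    led$transpiration[d] <- transp_today
    led$dstorage[d] <- w1 - w0

    if (!is.na(maturity)) {
      led <- led[seq_len(d), ]
      break
    }
  }

  daily <- data.frame(
    date = weather$date[r_used], doy = weather$doy[r_used],
    phase = r_phase[r_used], tt = r_tt[r_used], cum_tt = r_cumtt[r_used],
    lai = r_lai[r_used], dbiomass = r_db[r_used], biomass = r_bio[r_used],
    transpiration = r_tr[r_used], waterSD = r_wsd[r_used],
    pasw = r_pasw[r_used], rain = weather$rain[r_used]
  )
  failed <- stress_kill || is.na(anthesis)
  dry_yield <- if (failed) NA_real_ else grain_mass * 0.01 # g m-2 -> Mg ha-1
  structure(list(
    daily = daily,
    ledger = led,
    hourly_vpd = vpd_mat[r_used, , drop = FALSE],
    hourly_transp = tr_mat[r_used, , drop = FALSE],
    sowing_doy = sow_doy,
    anthesis_doy = anthesis,
    maturity_doy = maturity,
    reached_grain_fill = reached_gf,
    grain_number_m2 = grain_n_m2,
    dry_yield = dry_yield,
    yield = if (is.na(dry_yield)) NA_real_ else reported_yield(dry_yield),
    total_transpiration = crop_transp,
    biomass_at_flowering = biomass_fl,
    transp_at_flowering = transp_fl,
    pasw_at_flowering = pasw_fl,
    final_biomass = biomass,
    failed = failed,
    archetype = attr(weather, "archetype")
  ), class = "lt_season")
}

#' @export
print.lt_season <- function(x, ...) {
  cat("<lt_season>",
      if (x$failed) "FAILED (vegetative stage not completed)" else "", "\n")
  cat(sprintf("  sowing doy %d | anthesis %s | maturity %s\n",
              x$sowing_doy,
              ifelse(is.na(x$anthesis_doy), "-", x$anthesis_doy),
              ifelse(is.na(x$maturity_doy), "-", x$maturity_doy)))
  cat(sprintf("  yield (12.5%% moisture): %s Mg/ha | transpiration %.0f mm\n",
              ifelse(is.na(x$yield), "NA", sprintf("%.2f", x$yield)),
              x$total_transpiration))
  invisible(x)
}
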
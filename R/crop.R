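PHASES <- c("germination", "emergence", "end_juvenile", "floral_init",
            "flag_leaf", "flowering", "start_grain_fill", "end_grain_fill",
            "maturity")

#' Define a sorghum cultivar
#'
#' A cultivar bundles the trait parameter (the hourly limited-transpiration
#' cap), the maturity group, and the growth/development parameters. Maturity
#' groups short/medium/full carry 15/17/19 total leaves; they differ in the
#' thermal-time target from end of the juvenile phase to floral initiation
#' (`tt_endjuv_to_init`) and in the leaf-area logistic (`tpla_inflection`,
#' maximum plant leaf area), so fuller-season groups flower later and carry
#' more leaf area. The nine phase targets are package defaults (documented
#' assumptions; the short/medium/full ordering is fixed by leaf number).
#' `photoperiod_slope = 0` reflects a photoperiod-insensitive calibrated
#' hybrid; `dm_per_seed = 0.00099` g is the calibrated grain-set parameter.
#'
#' @param maturity `"short"`, `"medium"` or `"full"`.
#' @param transp_cap hourly transpiration cap, mm h-1: a value in
#'   [0.2, 0.9] for an LT phenotype, or `Inf` for non-LT.
#' @param ... overrides for any default parameter listed below.
#' @return an object of class `lt_cultivar` (a named list).
#' @examples
#' cv <- cultivar("short", transp_cap = 0.9)
#' cv$leaf_no
#' @export
cultivar <- function(maturity = c("short", "medium", "full"),
                     transp_cap = Inf, ...) {
  maturity <- match.arg(maturity)
  i <- match(maturity, c("short", "medium", "full"))
  leaf_no <- c(15L, 17L, 19L)[i]
  if (!(is.infinite(transp_cap) ||
        (transp_cap >= 0.2 && transp_cap <= 0.9))) {
    stop("transp_cap must be in [0.2, 0.9] mm/h for LT, or Inf for non-LT",
         call. = FALSE)
  }
  p <- list(
    maturity = maturity,
    leaf_no = leaf_no,
    transp_cap = transp_cap,
    # phase thermal-time targets, deg C d (sowing -> maturity)
    tt_sow_germ = 30, tt_germ_emerg = 50, tt_emerg_endjuv = 200,
    tt_endjuv_to_init = c(150, 230, 310)[i],
    tt_init_flag = c(280, 320, 360)[i],
    tt_flag_flower = 100, tt_flower_sgf = 120,
    tt_sgf_egf = 680, tt_egf_mat = 60,
    photoperiod_slope = 0,   # deg C d per hour above the threshold
    pp_threshold = 12.5,     # h
    # leaf area (TPLA logistic): max plant leaf area m2, rate, inflection
    tpla_max = 0.0016 * leaf_no^2,
    tpla_prod_coef = 0.012,
    tpla_inflection = c(280, 320, 360)[i],
    tillers = 0.3,
    # growth / grain
    rue = 1.25,              # g MJ-1
    k = 0.5,                 # light extinction
    te_coeff = 9,            # Pa
    dm_per_seed = 0.00099,   # g per seed (on mean FI->SGF growth rate)
    grain_fill_rate_mg = 0.7, # mg grain-1 d-1 potential
    stem_reserve_frac = 0.2, # remobilizable share of stem mass
    tbase = 11, topt = 30, tceil = 42
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown cultivar parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(dots)] <- dots
  structure(p, class = "lt_cultivar")
}

#' Define crop management
#'
#' @param sowing_date `"05-01"`, `"05-15"` or `"06-01"` (month-day).
#' @param density plant density, plants m-2 (6-17 across the belt).
#' @param row_spacing_mm row spacing (default 760 mm).
#' @param sowing_depth_mm sowing depth (default 20 mm).
#' @param initial_fasw initial fraction of plant-available soil water on
#'   1 January (0.6 for application runs, 0.7 for evaluation-style runs).
#' @param latitude site latitude, degrees (drives daylength).
#' @return an object of class `lt_management`.
#' @export
management <- function(sowing_date = c("05-01", "05-15", "06-01"),
                       density = 8, row_spacing_mm = 760,
                       sowing_depth_mm = 20, initial_fasw = 0.6,
                       latitude = 38.5) {
  sowing_date <- match.arg(sowing_date)
  stopifnot(density >= 1, initial_fasw >= 0, initial_fasw <= 1)
  structure(list(sowing_date = sowing_date, density = density,
                 row_spacing_mm = row_spacing_mm,
                 sowing_depth_mm = sowing_depth_mm,
                 initial_fasw = initial_fasw, latitude = latitude),
            class = "lt_management")
}

# cumulative phase targets from sowing for a cultivar, with the
# photoperiod extension applied to the end-juvenile -> floral-init phase
phase_targets <- function(cv, pp_extension = 0) {
  tt <- c(cv$tt_sow_germ, cv$tt_germ_emerg, cv$tt_emerg_endjuv,
          cv$tt_endjuv_to_init + pp_extension, cv$tt_init_flag,
          cv$tt_flag_flower, cv$tt_flower_sgf, cv$tt_sgf_egf, cv$tt_egf_mat)
  stats::setNames(cumsum(tt), PHASES)
}

#' Advance phenology by one day of thermal time
#'
#' The phase boundary from end-juvenile to floral initiation is extended by
#' `photoperiod_slope * max(0, daylength - threshold)` degree-days; with the
#' calibrated slope of 0 all targets are fixed. Water stress does not delay
#' development (stress acts on growth only), which keeps the centesimal
#' thermal-time axis well defined.
#'
#' @param cum_tt cumulative thermal time from sowing after today, deg C d.
#' @param cv an `lt_cultivar`.
#' @param daylength today's daylength, hours.
#' @return list with `phase` (index 0 = sown, 1..9 = boundaries passed,
#'   see `PHASES`) and `phase_name`.
#' @export
advance_phenology <- function(cum_tt, cv, daylength = 12) {
  ext <- cv$photoperiod_slope * max(0, daylength - cv$pp_threshold)
  tg <- phase_targets(cv, ext)
  phase <- sum(cum_tt >= tg)
  list(phase = phase,
       phase_name = if (phase == 0) "sown" else PHASES[phase])
}

#' Canopy leaf area from the TPLA logistic
#'
#' Per-plant total leaf area follows
#' `tpla_max (1 + tillers) / (1 + exp(-coef (tt - inflection)))` on thermal
#' time since emergence; LAI is the per-plant area times density. After
#' flowering the canopy senesces linearly to zero at maturity.
#'
#' @param tt_since_emergence thermal time since emergence, deg C d.
#' @param cv an `lt_cultivar`.
#' @param density plants m-2.
#' @param tt_since_flowering thermal time since flowering (0 before), used
#'   for senescence.
#' @param lai_at_flowering LAI recorded at flowering (for senescence).
#' @return leaf area index.
#' @export
leaf_area <- function(tt_since_emergence, cv, density,
                      tt_since_flowering = 0, lai_at_flowering = NULL) {
  if (tt_since_flowering > 0 && !is.null(lai_at_flowering)) {
    tt_flower_mat <- cv$tt_flower_sgf + cv$tt_sgf_egf + cv$tt_egf_mat
    return(max(0, lai_at_flowering * (1 - tt_since_flowering / tt_flower_mat)))
  }
  if (tt_since_emergence < 0) return(0)
  plant_area <- cv$tpla_max * (1 + cv$tillers) /
    (1 + exp(-cv$tpla_prod_coef * (tt_since_emergence - cv$tpla_inflection)))
  plant_area * density
}

#' Grain number from pre-anthesis growth rate
#'
#' Grain number per plant is the mean per-plant biomass growth rate between
#' floral initiation and the start of grain filling divided by
#' `dm_per_seed`; dividing the accumulated biomass by the phase duration in
#' days is the plant-basis correction that converts accumulation to a rate.
#'
#' @param biomass_fi_sgf biomass accumulated FI -> start of grain fill,
#'   g per plant.
#' @param n_days duration of that window, days.
#' @param dm_per_seed g of pre-anthesis growth rate per grain set.
#' @return grains per plant.
#' @export
grain_number <- function(biomass_fi_sgf, n_days, dm_per_seed = 0.00099) {
  stopifnot(n_days >= 1)
  (biomass_fi_sgf / n_days) / dm_per_seed
}

#' Convert dry grain yield to reported yield at 12.5\% moisture
#'
#' @param dry_yield dry yield, Mg ha-1.
#' @return reported yield, Mg ha-1 (`dry / (1 - 0.125)`).
#' @export
reported_yield <- function(dry_yield) dry_yield / (1 - 0.125)

#' Grain number and dry yield of a completed season
#'
#' @param season an `lt_season` result from [run_season()].
#' @return list with `grain_number_m2` and `dry_yield` (Mg ha-1).
#' @export
grain_yield <- function(season) {
  if (!isTRUE(season$reached_grain_fill)) {
    stop("season did not reach the start of grain fill; no grain set",
         call. = FALSE)
  }
  list(grain_number_m2 = season$grain_number_m2,
       dry_yield = season$dry_yield)
}
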
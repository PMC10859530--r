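#' Define a trait x maturity x planting x site x year factorial
#'
#' The design crosses the trait (non-LT vs an LT cap), maturity group,
#' planting date, site and year. Every cell of a site-year shares the same
#' weather realisation and soil initialisation, so the LT/non-LT contrast
#' is exactly paired; per-season seeds derive deterministically from the
#' master seed, site and year.
#'
#' @param sites a data frame from [generate_gradient_sites()] (or a subset).
#' @param n_years simulated years per site.
#' @param traits named numeric vector of hourly caps (`Inf` = non-LT),
#'   default `c(nonLT = Inf, LT = 0.9)`.
#' @param maturities subset of `c("short", "medium", "full")`.
#' @param plantings subset of `c("05-01", "05-15", "06-01")`.
#' @param initial_fasw initial available-water fraction on 1 January.
#' @param seed master seed.
#' @return an object of class `lt_design` (list of the above).
#' @export
factorial_design <- function(sites, n_years = 5,
                             traits = c(nonLT = Inf, LT = 0.9),
                             maturities = c("short", "medium", "full"),
                             plantings = c("05-01", "05-15", "06-01"),
                             initial_fasw = 0.6, seed = 1L) {
  stopifnot(nrow(sites) >= 1, n_years >= 1, length(traits) >= 1)
  structure(list(sites = sites, n_years = n_years, traits = traits,
                 maturities = maturities, plantings = plantings,
                 initial_fasw = initial_fasw, seed = as.integer(seed)),
            class = "lt_design")
}

#' Run the full factorial experiment
#'
#' One season simulation per design cell and year. Failed seasons are
#' flagged, never dropped. Water productivity (yield over total
#' transpiration) is reported for non-failed seasons only.
#'
#' @param design an [factorial_design()] object.
#' @param keep_trajectories if `TRUE`, attach the centesimal stress
#'   trajectory matrix of the *non-LT* runs (for envirotyping) as attribute
#'   `"trajectories"` plus a row index `"trajectory_rows"`.
#' @return a data frame with one row per (site, year, trait, maturity,
#'   planting): design labels, the generating archetype, sowing/anthesis/
#'   maturity days, yield (12.5\% moisture, Mg ha-1), total transpiration
#'   (mm), biomass/transpiration/available water at flowering, water
#'   productivity (Mg ha-1 mm-1) and the `failed` flag.
#' @export
run_factorial <- function(design, keep_trajectories = FALSE) {
  d <- design
  rows <- list()
  trajs <- list()
  for (si in seq_len(nrow(d$sites))) {
    site <- d$sites[si, ]
    soil0 <- make_soil(site$texture, site$depth_cm)
    archs <- draw_site_archetypes(site, d$n_years, d$seed)
    for (yr in seq_len(d$n_years)) {
      wth <- generate_season(archetype(archs[yr]),
                             year_index = derive_seed(d$seed, si, yr) %% 10000L,
                             seed = d$seed)
      for (mat in d$maturities) for (pl in d$plantings) {
        mgmt <- management(pl, density = site$density,
                           initial_fasw = d$initial_fasw)
        for (ti in seq_along(d$traits)) {
          cv <- cultivar(mat, transp_cap = d$traits[[ti]])
          s <- tryCatch(run_season(wth, soil0, cv, mgmt),
                        error = function(e) e)
          if (inherits(s, "error")) {
            warning(sprintf("cell site %s year %d %s/%s/%s failed: %s",
                            site$site, yr, names(d$traits)[ti], mat, pl,
                            conditionMessage(s)))
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            site = site$site, year = yr, archetype = archs[yr],
            trait = names(d$traits)[ti], transp_cap = d$traits[[ti]],
            maturity = mat, planting = pl,
            sowing_doy = s$sowing_doy, anthesis_doy = s$anthesis_doy,
            maturity_doy = if (is.na(s$maturity_doy)) NA_integer_
                           else s$maturity_doy,
            yield = s$yield, total_transpiration = s$total_transpiration,
            biomass_at_flowering = s$biomass_at_flowering,
            transp_at_flowering = s$transp_at_flowering,
            pasw_at_flowering = s$pasw_at_flowering,
            water_productivity = if (s$failed || s$total_transpiration <= 0)
              NA_real_ else s$yield / s$total_transpiration,
            season_rain = season_rain(wth),
            failed = s$failed
          )
          if (keep_trajectories && names(d$traits)[ti] == "nonLT" &&
              !s$failed) {
            trajs[[length(trajs) + 1L]] <-
              list(row = length(rows), traj = stress_trajectory(s))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_trajectories) {
    attr(out, "trajectories") <- do.call(rbind, lapply(trajs, `[[`, "traj"))
    attr(out, "trajectory_rows") <- vapply(trajs, `[[`, numeric(1), "row")
  }
  out
}

#' Relative change of LT over paired non-LT runs
#'
#' Pairs rows that differ only in trait and computes
#' `100 (LT - nonLT) / nonLT` per pair for the chosen outcome, pair first,
#' then averages over any grouping columns. Pairs with a failed or
#' zero-yield baseline are excluded (and counted).
#'
#' @param table output of [run_factorial()].
#' @param outcome outcome column, default `"yield"`.
#' @param by character vector of grouping columns (e.g. `"archetype"`,
#'   `"maturity"`); `NULL` for the overall mean.
#' @param lt_trait,baseline trait labels to compare.
#' @return a data frame of group means, standard deviations and pair
#'   counts; attribute `"excluded"` holds the number of dropped pairs.
#' @export
relative_change <- function(table, outcome = "yield", by = "archetype",
                            lt_trait = "LT", baseline = "nonLT") {
  key <- c("site", "year", "maturity", "planting")
  lt <- table[table$trait == lt_trait, ]
  nl <- table[table$trait == baseline, ]
  m <- merge(nl, lt, by = key, suffixes = c(".non", ".lt"))
  bad <- m$failed.non | m$failed.lt | is.na(m[[paste0(outcome, ".non")]]) |
    is.na(m[[paste0(outcome, ".lt")]]) | m[[paste0(outcome, ".non")]] == 0
  excl <- sum(bad)
  m <- m[!bad, ]
  m$rel <- 100 * (m[[paste0(outcome, ".lt")]] - m[[paste0(outcome, ".non")]]) /
    m[[paste0(outcome, ".non")]]
  if (is.null(by)) {
    out <- data.frame(mean_rel = mean(m$rel), sd_rel = stats::sd(m$rel),
                      n = nrow(m))
  } else {
    bycols <- lapply(by, function(b) {
      if (b %in% names(m)) m[[b]] else m[[paste0(b, ".non")]]
    })
    names(bycols) <- by
    agg <- stats::aggregate(m$rel, by = bycols,
                            FUN = function(v) c(mean = mean(v),
                                                sd = stats::sd(v),
                                                n = length(v)))
    out <- cbind(agg[by], as.data.frame(agg$x))
    names(out) <- c(by, "mean_rel", "sd_rel", "n")
  }
  attr(out, "excluded") <- excl
  out
}

#' Sensitivity of the LT yield effect to initial soil moisture
#'
#' Re-runs paired LT/non-LT seasons at each initial available-water level
#' (the LT cap held at `cap`), on one site, and summarises the relative
#' yield change per level across years.
#'
#' @param site one row of [generate_gradient_sites()] (a representative,
#'   drought-prone location).
#' @param levels initial available-water fractions, default
#'   `seq(0.2, 0.9, 0.1)`.
#' @param n_years years per level.
#' @param cap LT cap held fixed, mm h-1.
#' @param maturity,planting management held fixed.
#' @param seed master seed (same weather across levels).
#' @return data frame with `level`, `mean_rel`, `sd_rel`, `n` (non-failed
#'   pairs).
#' @export
sensitivity_initial_moisture <- function(site, levels = seq(0.2, 0.9, 0.1),
                                         n_years = 15, cap = 0.9,
                                         maturity = "medium",
                                         planting = "05-15", seed = 1L) {
  stopifnot(all(levels >= 0 & levels <= 1))
  archs <- draw_site_archetypes(site, n_years, seed)
  soil0 <- make_soil(site$texture, site$depth_cm)
  out <- lapply(levels, function(lv) {
    rel <- numeric(0)
    for (yr in seq_len(n_years)) {
      wth <- generate_season(archetype(archs[yr]), yr, seed)
      mgmt <- management(planting, density = site$density,
                        initial_fasw = lv)
      sn <- run_season(wth, soil0, cultivar(maturity, Inf), mgmt)
      sl <- run_season(wth, soil0, cultivar(maturity, cap), mgmt)
      if (sn$failed || sl$failed || sn$yield == 0) next
      rel <- c(rel, 100 * (sl$yield - sn$yield) / sn$yield)
    }
    data.frame(level = lv, mean_rel = mean(rel), sd_rel = stats::sd(rel),
               n = length(rel))
  })
  do.call(rbind, out)
}

#' Sensitivity of the LT yield effect to the cap value
#'
#' Paired LT/non-LT seasons for each cap in `caps` (initial moisture held
#' at `initial_fasw`), summarised per cap and per generating weather
#' archetype.
#'
#' @param site one row of [generate_gradient_sites()].
#' @param caps LT cap values, default `seq(0.2, 0.9, 0.1)`.
#' @param n_years years per cap.
#' @param initial_fasw initial available-water fraction (default 0.6).
#' @param maturity,planting management held fixed.
#' @param seed master seed.
#' @return data frame with `cap`, `archetype`, `mean_rel`, `sd_rel`, `n`.
#' @export
sensitivity_lt_threshold <- function(site, caps = seq(0.2, 0.9, 0.1),
                                     n_years = 15, initial_fasw = 0.6,
                                     maturity = "medium", planting = "05-15",
                                     seed = 1L) {
  stopifnot(all(caps >= 0.2 & caps <= 0.9))
  archs <- draw_site_archetypes(site, n_years, seed)
  soil0 <- make_soil(site$texture, site$depth_cm)
  mgmt <- management(planting, density = site$density,
                    initial_fasw = initial_fasw)
  base <- lapply(seq_len(n_years), function(yr) {
    wth <- generate_season(archetype(archs[yr]), yr, seed)
    list(w = wth, non = run_season(wth, soil0, cultivar(maturity, Inf), mgmt))
  })
  out <- list()
  for (cap in caps) {
    rel <- data.frame(archetype = character(0), rel = numeric(0))
    for (yr in seq_len(n_years)) {
      sn <- base[[yr]]$non
      sl <- run_season(base[[yr]]$w, soil0, cultivar(maturity, cap), mgmt)
      if (sn$failed || sl$failed || sn$yield == 0) next
      rel <- rbind(rel, data.frame(archetype = archs[yr],
                                   rel = 100 * (sl$yield - sn$yield) /
                                     sn$yield))
    }
    agg <- stats::aggregate(rel$rel, by = list(archetype = rel$archetype),
                            FUN = function(v) c(mean = mean(v),
                                                sd = stats::sd(v),
                                                n = length(v)))
    out[[length(out) + 1L]] <- cbind(cap = cap, agg["archetype"],
                                     as.data.frame(agg$x))
  }
  out <- do.call(rbind, out)
  names(out) <- c("cap", "archetype", "mean_rel", "sd_rel", "n")
  rownames(out) <- NULL
  out
}

#' Best maturity x planting combination per site
#'
#' The argmax over design cells of the across-year mean yield, per site and
#' trait. Failed seasons are treated as missing. Ties break toward earlier
#' planting, then shorter maturity.
#'
#' @param table output of [run_factorial()].
#' @return data frame with one row per (site, trait): the winning
#'   `maturity`, `planting` and its mean yield; sites where all cells
#'   failed carry `NA` and are flagged.
#' @export
best_combination <- function(table) {
  mat_rank <- c(short = 1, medium = 2, full = 3)
  out <- list()
  for (s in unique(table$site)) for (tr in unique(table$trait)) {
    sub <- table[table$site == s & table$trait == tr, ]
    sub$yield[sub$failed] <- NA
    agg <- stats::aggregate(yield ~ maturity + planting, data = sub,
                            FUN = function(v) mean(v, na.rm = TRUE),
                            na.action = stats::na.pass)
    agg <- agg[is.finite(agg$yield), ]
    if (!nrow(agg)) {
      out[[length(out) + 1L]] <- data.frame(
        site = s, trait = tr, maturity = NA, planting = NA,
        mean_yield = NA_real_, all_failed = TRUE)
      next
    }
    agg <- agg[order(-agg$yield, agg$planting, mat_rank[agg$maturity]), ]
    out[[length(out) + 1L]] <- data.frame(
      site = s, trait = tr, maturity = agg$maturity[1],
      planting = agg$planting[1], mean_yield = agg$yield[1],
      all_failed = FALSE)
  }
  do.call(rbind, out)
}
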
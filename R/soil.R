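# Pedotransfer-style lookup of volumetric water-holding limits by texture
# class (LL15 = wilting point, DUL = drained upper limit, SAT = saturation).
# Values are typical published ranges for each USDA class; the lookup stands
# in for a full pedotransfer run, which is outside this package's scope.
SOIL_TEXTURES <- data.frame(
  texture = c("sand", "loamy sand", "sandy loam", "loam", "silty loam",
              "silt loam", "silty clay loam", "clay loam", "silty clay",
              "clay"),
  ll15 = c(0.05, 0.06, 0.08, 0.11, 0.12, 0.12, 0.15, 0.16, 0.17, 0.18),
  dul  = c(0.14, 0.16, 0.20, 0.26, 0.28, 0.28, 0.32, 0.32, 0.33, 0.35),
  sat  = c(0.40, 0.41, 0.42, 0.45, 0.46, 0.46, 0.47, 0.47, 0.48, 0.50),
  stringsAsFactors = FALSE
)

#' Build a layered soil profile from a texture class
#'
#' Looks up LL15/DUL/SAT for the texture class and lays out layers
#' (150, 150, then 300 mm) down to `depth_cm`. The root-extraction
#' coefficient `kl` decays with depth: 0.07, 0.05 and 0.03 per day for the
#' upper, middle and lower thirds of the profile, the usual depth pattern
#' for sorghum water uptake. Runoff, drainage and soil-evaporation
#' parameters are carried as attributes and can be overridden.
#'
#' @param texture_class one of the classes in the documented lookup table
#'   (e.g. "sandy loam", "loam", "silty clay loam", "clay").
#' @param depth_cm total profile depth in cm.
#' @param runoff_threshold_mm daily rain below which no runoff occurs.
#' @param runoff_frac fraction of the rain excess above the threshold that
#'   runs off.
#' @param drain_coef fraction of above-DUL water draining to the next layer
#'   per day.
#' @param evap_u_mm stage-I cumulative soil evaporation limit (mm).
#' @param evap_cona stage-II soil evaporation coefficient (mm d^-1/2).
#' @return a `data.frame` of class `lt_soil` with columns `thickness_mm`,
#'   `ll15`, `dul`, `sat`, `kl`, `sw` (initialised at LL15).
#' @examples
#' s <- make_soil("clay", 200)
#' sum(s$thickness_mm)
#' @export
make_soil <- function(texture_class, depth_cm = 200,
                      runoff_threshold_mm = 15, runoff_frac = 0.35,
                      drain_coef = 0.5, evap_u_mm = 6, evap_cona = 3.5) {
  row <- SOIL_TEXTURES[SOIL_TEXTURES$texture == tolower(texture_class), ]
  if (nrow(row) != 1) {
    stop("unknown texture class '", texture_class, "'; known classes: ",
         paste(SOIL_TEXTURES$texture, collapse = ", "), call. = FALSE)
  }
  depth_mm <- depth_cm * 10
  th <- c(150, 150)
  while (sum(th) < depth_mm) th <- c(th, min(300, depth_mm - sum(th)))
  th <- th[th > 0]
  if (sum(th) > depth_mm) th[length(th)] <- th[length(th)] - (sum(th) - depth_mm)
  nb <- length(th)
  centre <- cumsum(th) - th / 2
  kl <- ifelse(centre <= depth_mm / 3, 0.07,
               ifelse(centre <= 2 * depth_mm / 3, 0.05, 0.03))
  soil <- data.frame(
    thickness_mm = th,
    ll15 = rep(row$ll15, nb), dul = rep(row$dul, nb), sat = rep(row$sat, nb),
    kl = kl, sw = rep(row$ll15, nb)
  )
  attr(soil, "texture") <- tolower(texture_class)
  attr(soil, "runoff_threshold_mm") <- runoff_threshold_mm
  attr(soil, "runoff_frac") <- runoff_frac
  attr(soil, "drain_coef") <- drain_coef
  attr(soil, "evap_u_mm") <- evap_u_mm
  attr(soil, "evap_cona") <- evap_cona
  attr(soil, "evap_cum") <- 0      # cumulative evaporation since last wetting
  class(soil) <- c("lt_soil", "data.frame")
  validate_soil(soil)
}

validate_soil <- function(soil) {
  stopifnot(nrow(soil) >= 1)
  with(soil, {
    if (!all(0 < ll15 & ll15 < dul & dul < sat & sat < 1)) {
      stop("soil layers must satisfy 0 < LL15 < DUL < SAT < 1", call. = FALSE)
    }
    if (!all(kl > 0 & kl <= 0.12)) {
      stop("kl must lie in (0, 0.12]", call. = FALSE)
    }
  })
  soil
}

#' Plant-available water capacity of a profile (mm)
#'
#' Sum over layers of (DUL - LL15) x thickness.
#' @param soil an `lt_soil` profile.
#' @export
pawc <- function(soil) sum((soil$dul - soil$ll15) * soil$thickness_mm)

#' Current plant-available soil water (mm)
#'
#' Sum over layers of max(0, sw - LL15) x thickness.
#' @param soil an `lt_soil` profile.
#' @export
plant_available_water <- function(soil) {
  sum(pmax(0, soil$sw - soil$ll15) * soil$thickness_mm)
}

# total stored water, mm (used for conservation accounting)
profile_water <- function(soil) sum(soil$sw * soil$thickness_mm)

#' Set initial soil moisture as a fraction of plant-available capacity
#'
#' Every layer gets `sw = ll15 + fraction * (dul - ll15)`; `fraction = 0.6`
#' is the usual application setting and 0.7 the usual evaluation setting.
#'
#' @param soil an `lt_soil` profile.
#' @param fraction available-water fraction in [0, 1].
#' @return the profile with `sw` set.
#' @export
initialize_moisture <- function(soil, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  soil$sw <- soil$ll15 + fraction * (soil$dul - soil$ll15)
  attr(soil, "evap_cum") <- 0
  soil
}
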
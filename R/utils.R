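#' @keywords internal
#' @importFrom stats approx aggregate AIC anova as.formula logLik na.omit
#'   pchisq rgamma rnorm runif sd setNames terms median na.pass
#' @importFrom utils read.csv write.csv read.table capture.output
#' @importFrom cluster pam clara
#' @importFrom lmerTest lmer
#' @importFrom emmeans emmeans contrast
#' @importFrom multcomp cld
"_PACKAGE"

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash used to give every stochastic unit (a season,
#' a site, a replicate) its own RNG stream while keeping the whole experiment
#' reproducible from one master seed. Arithmetic stays below 2^53 so the
#' result is exact in double precision, and the value is reduced modulo
#' 2^31 - 1 to remain a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... further integer stream identifiers (year index, site index...).
#' @return a single integer in [1, 2147483646].
#' @export
derive_seed <- function(master, ...) {
  ids <- c(master, ...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  h <- 0
  for (x in as.numeric(ids)) {
    h <- (h * 69069 + (x %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate an expression under a locally-set RNG seed, restoring the caller's
# RNG state afterwards (same convention as simulate() methods).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Day-of-year bounds of the May-October growing season (365-day year).
SEASON_START_DOY <- 121L # May 1
SEASON_END_DOY <- 304L   # Oct 31

# Astronomical daylength (hours) from latitude (deg) and day of year,
# standard CBM/solar-declination formula.
daylength_hours <- function(doy, latitude = 38.5) {
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  lat <- latitude * pi / 180
  x <- -tan(lat) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  2 * acos(x) * 12 / pi
}
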
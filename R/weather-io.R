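#' Validate a daily weather series
#'
#' Checks the physical invariants (tmax >= tmin, non-negative radiation and
#' rain) and date contiguity; errors name the first offending row/date.
#'
#' @param weather a data frame with columns `date`, `tmax`, `tmin`, `radn`,
#'   `rain` (a `doy` column is recomputed if absent).
#' @return the validated series, classed `lt_weather`, invisibly usable.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmax", "tmin", "radn", "rain")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop("weather is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  weather$date <- as.Date(weather$date)
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad)) {
    stop(sprintf("tmax < tmin at row %d (%s)", bad[1],
                 format(weather$date[bad[1]])), call. = FALSE)
  }
  bad <- which(weather$radn < 0 | weather$rain < 0)
  if (length(bad)) {
    stop(sprintf("negative radn or rain at row %d (%s)", bad[1],
                 format(weather$date[bad[1]])), call. = FALSE)
  }
  if (nrow(weather) > 1) {
    gaps <- which(diff(as.integer(weather$date)) != 1L)
    if (length(gaps)) {
      stop(sprintf("dates not contiguous after %s",
                   format(weather$date[gaps[1]])), call. = FALSE)
    }
  }
  if (is.null(weather$doy)) {
    weather$doy <- as.integer(format(weather$date, "%j"))
  }
  if (!inherits(weather, "lt_weather")) {
    class(weather) <- c("lt_weather", class(weather))
  }
  weather
}

#' Read / write daily weather files
#'
#' Two dialects are supported: `"csv"` with header
#' `date,tmax,tmin,radn,rain` and ISO dates, and `"met"`, an APSIM-style
#' text format with a `[weather.met.weather]` header block and space-
#' separated columns `year day radn maxt mint rain`. Write-then-read
#' round-trips are value-identical.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"met"`.
#' @param weather an `lt_weather`/data frame for writing.
#' @return `read_weather` returns a validated `lt_weather` data frame;
#'   `write_weather` returns `path` invisibly.
#' @export
read_weather <- function(path, dialect = c("csv", "met")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    w <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    hdr <- grep("^year\\s+day", lines)
    if (!length(hdr)) stop("no 'year day ...' column header in met file",
                           call. = FALSE)
    body <- lines[(hdr[1] + 2):length(lines)] # skip units line
    body <- body[nzchar(trimws(body))]
    con <- textConnection(body)
    on.exit(close(con), add = TRUE)
    d <- utils::read.table(con, col.names = c("year", "day", "radn",
                                              "maxt", "mint", "rain"))
    w <- data.frame(
      date = as.Date(d$day - 1, origin = paste0(d$year, "-01-01")),
      tmax = d$maxt, tmin = d$mint, radn = d$radn, rain = d$rain
    )
  }
  validate_weather(w)
}

#' @rdname read_weather
#' @export
write_weather <- function(weather, path, dialect = c("csv", "met")) {
  dialect <- match.arg(dialect)
  weather <- validate_weather(weather)
  if (dialect == "csv") {
    num <- function(x) sub("e", "E", sprintf("%.17g", x)) # exact round-trip
    utils::write.csv(
      data.frame(date = format(weather$date), tmax = num(weather$tmax),
                 tmin = num(weather$tmin), radn = num(weather$radn),
                 rain = num(weather$rain)),
      path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- c("[weather.met.weather]",
             "!synthetic weather series",
             "latitude = 38.5  (DECIMAL DEGREES)",
             "tav = 13.5 (oC)",
             "amp = 14.0 (oC)",
             "year day radn maxt mint rain",
             "()   ()  (MJ/m^2) (oC) (oC) (mm)")
    yr <- as.integer(format(weather$date, "%Y"))
    dy <- as.integer(format(weather$date, "%j"))
    rows <- sprintf("%d %d %.17g %.17g %.17g %.17g",
                    yr, dy, weather$radn, weather$tmax, weather$tmin,
                    weather$rain)
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}
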
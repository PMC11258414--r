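#' Relative humidity from dew point and air temperature
#'
#' Magnus-form relative humidity. The saturation vapour pressure ratio is
#' evaluated as \code{10^(7.591386 * (d2m/(d2m + 240.7263) -
#' t_air/(t_air + 240.7263)))}, expressed in percent. Values above 100
#' (dew point above air temperature, which does occur in gridded
#' reanalysis products) are clamped to 100 with a warning.
#'
#' @param d2m Dew-point temperature in degrees Celsius. Vectorised.
#' @param t_air Air temperature in degrees Celsius. Vectorised.
#' @return Relative humidity in percent, in (0, 100].
#' @examples
#' relative_humidity(d2m = 10, t_air = 20)
#' @export
relative_humidity <- function(d2m, t_air) {
  if (!is.numeric(d2m) || !is.numeric(t_air) ||
      any(!is.finite(d2m)) || any(!is.finite(t_air)))
    stop("`d2m` and `t_air` must be finite numeric values", call. = FALSE)
  if (any(t_air <= -240.7263) || any(d2m <= -240.7263))
    stop("temperatures must exceed -240.7263 degrees C (Magnus denominator)",
         call. = FALSE)
  rh <- 100 * 10^(7.591386 * (d2m / (d2m + 240.7263) -
                                t_air / (t_air + 240.7263)))
  if (any(rh > 100)) {
    warning("dew point above air temperature: relative humidity clamped to 100",
            call. = FALSE)
    rh <- pmin(rh, 100)
  }
  rh
}

#' Romanenko potential evapotranspiration
#'
#' Monthly potential evapotranspiration from the Romanenko temperature and
#' humidity approximation, \code{PET = 0.00006 * (100 - RH) * (25 + t_air)^2}.
#' The constant does not fix a depth unit; the result is only meaningful in
#' whatever common depth unit the precipitation series uses, since the two
#' enter the Aridity Index solely as a ratio.
#'
#' @param t_air Air temperature in degrees Celsius. Vectorised.
#' @param rh Relative humidity in percent, in [0, 100]. Vectorised.
#' @return Potential evapotranspiration per month (depth unit of the caller).
#' @examples
#' pet_romanenko(t_air = 25, rh = 50)  # 7.5
#' @export
pet_romanenko <- function(t_air, rh) {
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    stop("`rh` must lie in [0, 100]", call. = FALSE)
  if (!is.numeric(t_air) || any(!is.finite(t_air)))
    stop("`t_air` must be finite numeric", call. = FALSE)
  0.00006 * (100 - rh) * (25 + t_air)^2
}

#' Build a climate series object
#'
#' A climate series is a site-labelled table of monthly records with columns
#' \code{year}, \code{month}, \code{t_air} (deg C), \code{t_p} (precipitation
#' depth), \code{d2m} (dew point, deg C). Months must be unique within years
#' and contiguous within each year.
#'
#' @param site Site name (length-1 character).
#' @param records Data frame with columns year, month, t_air, t_p, d2m.
#' @return An object of class \code{climate_series}.
#' @export
climate_series <- function(site, records) {
  need <- c("year", "month", "t_air", "t_p", "d2m")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  records <- records[order(records$year, records$month), need, drop = FALSE]
  if (any(records$month < 1 | records$month > 12))
    stop("month must be in 1..12", call. = FALSE)
  if (anyDuplicated(records[c("year", "month")]))
    stop("duplicate (year, month) records", call. = FALSE)
  if (any(records$t_p < 0)) stop("t_p must be non-negative", call. = FALSE)
  for (y in unique(records$year)) {
    m <- sort(records$month[records$year == y])
    if (!all(diff(m) == 1L))
      stop("months within year ", y, " are not contiguous", call. = FALSE)
  }
  structure(list(site = site, records = records), class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat("Climate series for site", x$site, "-", nrow(x$records),
      "monthly records,", length(unique(x$records$year)), "year(s)\n")
  invisible(x)
}

complete_years <- function(records) {
  tab <- table(records$year)
  as.integer(names(tab)[tab == 12L])
}

#' Annual Aridity Index from a monthly climate series
#'
#' For each month, relative humidity is derived from dew point and air
#' temperature, then Romanenko potential evapotranspiration (PET) from
#' humidity and temperature. The Aridity Index (AI) is the ratio of total
#' precipitation to total PET. Only complete calendar years (12 months)
#' enter the computation.
#'
#' @param series A \code{\link{climate_series}}.
#' @param aggregation \code{"annual_mean"} (default) computes AI per calendar
#'   year and averages across years; \code{"pooled"} forms one ratio from the
#'   pooled multi-year sums.
#' @param years Optional vector restricting which calendar years are used
#'   (e.g. a single recent year).
#' @param thresholds Classification thresholds passed to
#'   \code{\link{classify_aridity}}.
#' @return A list of class \code{aridity_result} with elements \code{site},
#'   \code{AI}, \code{PET_annual} (mean annual PET), \code{RH_mean} (mean
#'   monthly relative humidity, percent), \code{aridity_class},
#'   \code{per_year} (data frame of yearly precipitation, PET and AI) and
#'   \code{aggregation}.
#' @export
aridity_index <- function(series, aggregation = c("annual_mean", "pooled"),
                          years = NULL,
                          thresholds = aridity_thresholds()) {
  stopifnot(inherits(series, "climate_series"))
  aggregation <- match.arg(aggregation)
  rec <- series$records
  keep_years <- complete_years(rec)
  if (!is.null(years)) keep_years <- intersect(keep_years, years)
  if (length(keep_years) == 0L)
    stop("no complete calendar year available for AI computation",
         call. = FALSE)
  rec <- rec[rec$year %in% keep_years, , drop = FALSE]
  rh <- suppressWarnings(relative_humidity(rec$d2m, rec$t_air))
  pet <- pet_romanenko(rec$t_air, rh)
  tp_y <- tapply(rec$t_p, rec$year, sum)
  pet_y <- tapply(pet, rec$year, sum)
  if (any(pet_y <= 0))
    stop("total PET is zero in at least one year: AI undefined", call. = FALSE)
  ai_y <- tp_y / pet_y
  ai <- if (aggregation == "annual_mean") mean(ai_y) else
    sum(tp_y) / sum(pet_y)
  structure(list(
    site = series$site,
    AI = unname(ai),
    PET_annual = unname(mean(pet_y)),
    RH_mean = unname(mean(rh)),
    aridity_class = classify_aridity(unname(ai), thresholds),
    per_year = data.frame(year = as.integer(names(tp_y)),
                          t_p = as.numeric(tp_y),
                          PET = as.numeric(pet_y),
                          AI = as.numeric(ai_y), row.names = NULL),
    aggregation = aggregation
  ), class = "aridity_result")
}

#' @export
print.aridity_result <- function(x, ...) {
  cat(sprintf("Site %s: AI = %.3f (%s), mean annual PET = %.3f, mean RH = %.1f%%\n",
              x$site, x$AI, x$aridity_class, x$PET_annual, x$RH_mean))
  invisible(x)
}

#' Default aridity classification thresholds
#'
#' Half-open AI bins: \code{[0, arid)} is arid, \code{[arid, semi_arid)} is
#' semi-arid, \code{[semi_arid, Inf)} is mesic. The defaults (0.10, 0.25)
#' place AI values of 0.04 and 0.07 in the arid class, 0.11 in semi-arid,
#' and 0.42 and 0.86 in mesic.
#'
#' @param arid Upper bound (exclusive) of the arid class.
#' @param semi_arid Upper bound (exclusive) of the semi-arid class.
#' @return Named numeric vector of thresholds.
#' @export
aridity_thresholds <- function(arid = 0.10, semi_arid = 0.25) {
  if (!(arid > 0 && semi_arid > arid))
    stop("thresholds must satisfy 0 < arid < semi_arid", call. = FALSE)
  c(arid = arid, semi_arid = semi_arid)
}

#' Classify an Aridity Index value
#'
#' @param ai Aridity Index value(s), non-negative.
#' @param thresholds See \code{\link{aridity_thresholds}}.
#' @return Character vector in \code{c("arid", "semi-arid", "mesic")}.
#' @examples
#' classify_aridity(c(0.04, 0.11, 0.42))
#' @export
classify_aridity <- function(ai, thresholds = aridity_thresholds()) {
  if (!is.numeric(ai) || any(!is.finite(ai)) || any(ai < 0))
    stop("`ai` must be finite and non-negative", call. = FALSE)
  ifelse(ai < thresholds[["arid"]], "arid",
         ifelse(ai < thresholds[["semi_arid"]], "semi-arid", "mesic"))
}

#' Read a climate table
#'
#' Reads a delimited table with one row per site-month and splits it into
#' one \code{\link{climate_series}} per site.
#'
#' @param path CSV/TSV file path.
#' @param sep Field separator (default comma; use \code{"\t"} for TSV).
#' @param columns Named character vector mapping the required names
#'   (site, year, month, t_air, t_p, d2m) to the file's column names.
#' @return Named list of \code{climate_series}, one per site.
#' @export
read_climate_table <- function(path, sep = ",",
                               columns = c(site = "site", year = "year",
                                           month = "month", t_air = "t_air",
                                           t_p = "t_p", d2m = "d2m")) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols))
    stop("climate table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  std <- data.frame(site = tab[[columns[["site"]]]],
                    year = as.integer(tab[[columns[["year"]]]]),
                    month = as.integer(tab[[columns[["month"]]]]),
                    t_air = as.numeric(tab[[columns[["t_air"]]]]),
                    t_p = as.numeric(tab[[columns[["t_p"]]]]),
                    d2m = as.numeric(tab[[columns[["d2m"]]]]))
  out <- lapply(split(std, std$site), function(d)
    climate_series(d$site[1], d[setdiff(names(d), "site")]))
  out[unique(std$site)]
}

#' Aridity summary table for a set of sites
#'
#' @param series_list Named list of \code{\link{climate_series}}.
#' @param ... Passed on to \code{\link{aridity_index}}.
#' @return Data frame with columns site, AI, PET_annual, RH_mean, class.
#' @export
aridity_table <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    r <- aridity_index(s, ...)
    data.frame(site = r$site, AI = r$AI, PET_annual = r$PET_annual,
               RH_mean = r$RH_mean, class = r$aridity_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an aridity table to TSV and JSON
#'
#' @param tab Data frame from \code{\link{aridity_table}}.
#' @param path Output path without extension; \code{.tsv} and \code{.json}
#'   files are written.
#' @return Invisibly, the two paths written.
#' @export
write_aridity_table <- function(tab, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
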
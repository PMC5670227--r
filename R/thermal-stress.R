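# Cumulative marine heat stress from temperature-logger series: daily means,
# anomalies against a site MMM, and Degree Heating Days/Weeks.

HABITATS <- c("intertidal", "subtidal", "reef_flat", "open", "unspecified")
DHD_RULES <- c("all_positive", "noaa_ge1")

#' Construct a temperature-logger series
#'
#' Holds sub-daily in situ temperature records for one site/habitat, as
#' produced by moored loggers sampling on a fixed cadence (default every
#' 15 minutes).
#'
#' @param timestamp `POSIXct` vector (local clock time), strictly increasing.
#' @param temperature_c Numeric water temperatures in degrees Celsius.
#' @param site_id Site label.
#' @param habitat One of `"intertidal"`, `"subtidal"`, `"reef_flat"`,
#'   `"open"`, `"unspecified"`.
#' @param nominal_interval Nominal sampling interval in minutes.
#' @param plausible Length-2 plausibility band in degrees C; records outside it
#'   are rejected (default -2 to 45).
#' @return A `temperature_series` data frame with columns `timestamp`,
#'   `temperature_c`.
#' @export
temperature_series <- function(timestamp, temperature_c, site_id,
                               habitat = "unspecified",
                               nominal_interval = 15,
                               plausible = c(-2, 45)) {
  habitat <- match.arg(habitat, HABITATS)
  if (length(timestamp) == 0L) stop_input("temperature series is empty")
  if (length(timestamp) != length(temperature_c)) {
    stop_input("timestamp and temperature_c lengths differ")
  }
  if (inherits(timestamp, "character")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  if (!inherits(timestamp, "POSIXct")) stop_input("timestamp must be POSIXct")
  if (anyNA(timestamp)) stop_input("timestamps contain NA")
  dt <- diff(as.numeric(timestamp))
  if (any(dt <= 0)) {
    stop_input("timestamps must be strictly increasing (unique); first ",
               "violation at record ", which(dt <= 0)[1] + 1L)
  }
  bad <- which(!is.na(temperature_c) &
                 (temperature_c < plausible[1] | temperature_c > plausible[2]))
  if (length(bad)) {
    stop_input("temperature outside plausibility band [", plausible[1], ", ",
               plausible[2], "] degC at record(s) ",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(
    data.frame(timestamp = timestamp, temperature_c = temperature_c),
    site_id = as.character(site_id), habitat = habitat,
    nominal_interval = nominal_interval,
    class = c("temperature_series", "data.frame")
  )
}

#' Site climatology (maximum monthly mean SST)
#'
#' The MMM is the long-term mean SST of the warmest month at a site and is the
#' baseline against which heat-stress anomalies are measured. The bleaching
#' threshold is conventionally MMM + 1 degC.
#'
#' @param site_id Site label.
#' @param mmm Maximum monthly mean SST in degrees C (must lie in (10, 40)).
#' @param source Free-text provenance, e.g. which climatology product or
#'   in-situ derivation supplied the value.
#' @return A `climatology` object.
#' @export
climatology <- function(site_id, mmm, source = "unspecified") {
  if (!is.numeric(mmm) || length(mmm) != 1L || is.na(mmm)) {
    stop_input("mmm must be a single number")
  }
  if (mmm <= 10 || mmm >= 40) stop_input("mmm = ", mmm, " outside (10, 40) degC")
  structure(list(site_id = as.character(site_id), mmm = mmm,
                 source = source),
            class = "climatology")
}

#' Daily mean temperatures from a sub-daily series
#'
#' Aggregates logger records to local-clock calendar days. A day is usable
#' only if it holds at least `min_coverage` of the nominal record count
#' (1440 / interval); under-covered days are flagged incomplete and carry no
#' mean, so downstream heat-stress sums stay a lower bound.
#'
#' @param series A [temperature_series()].
#' @param min_coverage Fraction in (0, 1] of the nominal daily record count
#'   required before a day gets a mean (default 0.75).
#' @return A `daily_series` data frame with columns `date`, `mean_c`,
#'   `n_records`, `complete`.
#' @export
daily_means <- function(series, min_coverage = 0.75) {
  if (!inherits(series, "temperature_series")) {
    stop_input("series must be a temperature_series")
  }
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1) {
    stop_input("min_coverage must lie in (0, 1]")
  }
  expected <- 1440 / attr(series, "nominal_interval")
  # local-clock day: take the printed date, no time-zone arithmetic
  day <- as.Date(format(series$timestamp, "%Y-%m-%d"))
  n <- tapply(series$temperature_c, day, function(x) sum(!is.na(x)))
  m <- tapply(series$temperature_c, day, mean, na.rm = TRUE)
  dates <- as.Date(names(n))
  o <- order(dates)
  dates <- dates[o]; n <- as.integer(n[o]); m <- as.numeric(m[o])
  complete <- n >= min_coverage * expected
  m[!complete] <- NA_real_
  if (!any(complete)) {
    warning("no day reaches min_coverage = ", min_coverage,
            "; daily series has zero usable entries", call. = FALSE)
  }
  structure(
    data.frame(date = dates, mean_c = m, n_records = n, complete = complete),
    site_id = attr(series, "site_id"), habitat = attr(series, "habitat"),
    class = c("daily_series", "data.frame")
  )
}

#' Daily SST anomalies relative to the site MMM
#'
#' anomaly(d) = daily mean(d) - MMM. Incomplete days propagate as missing.
#'
#' @param daily A `daily_series` from [daily_means()].
#' @param clim A [climatology()] for the same site.
#' @return An `anomaly_series` data frame with columns `date`, `anomaly_c`.
#' @export
anomaly_series <- function(daily, clim) {
  if (!inherits(daily, "daily_series")) stop_input("daily must be a daily_series")
  if (!inherits(clim, "climatology")) stop_input("clim must be a climatology")
  if (!identical(attr(daily, "site_id"), clim$site_id)) {
    stop_input("site mismatch: daily series is for '", attr(daily, "site_id"),
               "' but climatology is for '", clim$site_id, "'")
  }
  if (!any(daily$complete)) stop_input("daily series has no usable entries")
  structure(
    data.frame(date = daily$date, anomaly_c = daily$mean_c - clim$mmm),
    site_id = clim$site_id, mmm = clim$mmm,
    class = c("anomaly_series", "data.frame")
  )
}

dhd_contrib <- function(a, rule) {
  a[is.na(a)] <- 0
  switch(rule,
         all_positive = pmax(0, a),
         noaa_ge1     = ifelse(a >= 1, a, 0))
}

#' Accumulate Degree Heating Days over a trailing window
#'
#' DHD(t) sums daily anomaly contributions over the `window_days` calendar
#' days ending at t (dates in `(t - window_days, t]`, i.e. a reading exactly
#' `window_days + 1` days old, counting today's as 1 day old, contributes
#' nothing). Two accumulation rules are supported: `all_positive` sums every
#' positive anomaly; `noaa_ge1` sums only anomalies of at least 1 degC
#' (HotSpot convention: the full anomaly counts, not anomaly - 1). Calendar
#' days absent from the input contribute 0 and are listed in the gap report;
#' dates with fewer than `window_days` predecessors are flagged partial.
#'
#' @param anomalies An `anomaly_series` or data frame with columns `date`,
#'   `anomaly_c`, date-ordered.
#' @param rule `"all_positive"` (default) or `"noaa_ge1"`.
#' @param window_days Trailing window length in days (default 84 = 12 weeks).
#' @return A `dhd_series` data frame with columns `date`, `anomaly_c`, `dhd`,
#'   `dhw`, `partial_window`, `gap`; attribute `gap_report` lists missing or
#'   incomplete dates.
#' @export
accumulate_dhd <- function(anomalies, rule = c("all_positive", "noaa_ge1"),
                           window_days = 84) {
  rule <- match.arg(rule)
  if (!is.numeric(window_days) || length(window_days) != 1L ||
      window_days < 1 || window_days != round(window_days)) {
    stop_input("window_days must be an integer >= 1")
  }
  if (!all(c("date", "anomaly_c") %in% names(anomalies))) {
    stop_input("anomalies needs columns 'date' and 'anomaly_c'")
  }
  d <- as.Date(anomalies$date)
  if (is.unsorted(d, strictly = TRUE)) stop_input("anomaly dates must be ordered and unique")
  full <- seq(min(d), max(d), by = "day")
  a <- rep(NA_real_, length(full))
  a[match(d, full)] <- anomalies$anomaly_c
  contrib <- dhd_contrib(a, rule)
  cs <- cumsum(contrib)
  i <- seq_along(full)
  lag <- i - window_days
  dhd <- cs - ifelse(lag >= 1, cs[pmax(lag, 1)], 0)
  partial <- i < window_days
  gap <- is.na(a)
  structure(
    data.frame(date = full, anomaly_c = a, dhd = dhd, dhw = dhd / 7,
               partial_window = partial, gap = gap),
    rule = rule, window_days = window_days,
    gap_report = full[gap],
    site_id = attr(anomalies, "site_id"),
    class = c("dhd_series", "data.frame")
  )
}

#' Convert Degree Heating Days to Degree Heating Weeks
#'
#' @param dhd Non-negative DHD value(s) in degC-days.
#' @return DHW in degC-weeks (`dhd / 7`), unrounded.
#' @seealso [report_dhw()] for the 1-decimal reporting convention.
#' @export
dhd_to_dhw <- function(dhd) {
  if (any(is.na(dhd)) || any(dhd < 0)) stop_input("dhd must be non-negative")
  dhd / 7
}

#' Report DHW at 1-decimal precision
#'
#' Reporting convention: DHW is rounded *up* to one decimal so that the
#' bleaching-risk index is never understated (64.9 DHD reports as 9.3 DHW,
#' 16.4 DHD as 2.4 DHW).
#'
#' @param dhd Non-negative DHD value(s).
#' @return DHW rounded up to 1 decimal.
#' @export
report_dhw <- function(dhd) round_up_1dp(dhd_to_dhw(dhd))

#' Full heat-stress profile for one site
#'
#' Chains [daily_means()], [anomaly_series()] and [accumulate_dhd()] and adds
#' threshold-exceedance flags: `above_mmm` (daily mean strictly exceeds the
#' MMM) and `above_threshold` (exceeds the bleaching threshold MMM + 1 degC).
#'
#' @inheritParams daily_means
#' @inheritParams accumulate_dhd
#' @param clim A [climatology()].
#' @return A `heat_stress_profile` data frame with columns `date`,
#'   `daily_mean_c`, `anomaly_c`, `dhd`, `dhw`, `above_mmm`,
#'   `above_threshold`, `partial_window`.
#' @export
heat_stress_profile <- function(series, clim,
                                rule = c("all_positive", "noaa_ge1"),
                                window_days = 84, min_coverage = 0.75) {
  rule <- match.arg(rule)
  daily <- daily_means(series, min_coverage = min_coverage)
  anom <- anomaly_series(daily, clim)
  acc <- accumulate_dhd(anom, rule = rule, window_days = window_days)
  mean_c <- acc$anomaly_c + clim$mmm
  structure(
    data.frame(date = acc$date, daily_mean_c = mean_c,
               anomaly_c = acc$anomaly_c, dhd = acc$dhd, dhw = acc$dhw,
               above_mmm = !is.na(acc$anomaly_c) & acc$anomaly_c > 0,
               above_threshold = !is.na(acc$anomaly_c) & acc$anomaly_c > 1,
               partial_window = acc$partial_window),
    site_id = clim$site_id, habitat = attr(series, "habitat"),
    mmm_used = clim$mmm, rule = rule, window_days = window_days,
    gap_report = attr(acc, "gap_report"),
    class = c("heat_stress_profile", "data.frame")
  )
}

#' Summarise threshold exceedance and peak heat stress
#'
#' @param profile A [heat_stress_profile()].
#' @return A list with `site_id`, `n_days`, `days_above_mmm`,
#'   `days_above_threshold`, `max_anomaly`, `final_dhd`, `final_dhw`,
#'   `max_dhw`, `date_max_dhw`, `n_gap_days`, `rule`.
#' @export
exceedance_summary <- function(profile) {
  if (!inherits(profile, "heat_stress_profile")) {
    stop_input("profile must be a heat_stress_profile")
  }
  if (nrow(profile) == 0L) stop_input("empty profile")
  usable <- !is.na(profile$anomaly_c)
  imax <- which.max(profile$dhw)
  list(
    site_id = attr(profile, "site_id"),
    n_days = nrow(profile),
    days_above_mmm = sum(profile$above_mmm),
    days_above_threshold = sum(profile$above_threshold),
    max_anomaly = if (any(usable)) max(profile$anomaly_c[usable]) else NA_real_,
    final_dhd = profile$dhd[nrow(profile)],
    final_dhw = profile$dhw[nrow(profile)],
    max_dhw = profile$dhw[imax],
    date_max_dhw = profile$date[imax],
    n_gap_days = length(attr(profile, "gap_report")),
    rule = attr(profile, "rule")
  )
}
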
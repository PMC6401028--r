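# Weekly SST series: DHW accumulation, event heat-stress metrics and
# historical climate-variability metrics.

#' Construct and validate a weekly SST series
#'
#' @param site_id Site identifier.
#' @param week_start Vector of `Date` week-start dates at strict 7-day
#'   spacing (gaps of up to 2 missing weeks are linearly interpolated;
#'   larger gaps are rejected).
#' @param sst Weekly sea surface temperature in degrees C.
#' @param baseline Two-element integer vector, the climatology baseline
#'   years (inclusive); default `c(1985, 2009)`.
#' @return An `sst_series` object.
#' @export
sst_series <- function(site_id, week_start, sst, baseline = c(1985L, 2009L)) {
  week_start <- as.Date(week_start)
  ord <- order(week_start)
  week_start <- week_start[ord]
  sst <- as.numeric(sst)[ord]
  if (anyDuplicated(week_start)) stop_rp("duplicate week_start dates")
  gaps <- as.integer(diff(week_start))
  if (length(gaps) && any(gaps %% 7L != 0L)) {
    stop_rp("week_start dates must be aligned on a 7-day grid")
  }
  if (length(gaps) && any(gaps > 21L)) {
    stop_rp("gap of more than 2 missing weeks in SST series for %s", site_id)
  }
  full <- seq(week_start[1], week_start[length(week_start)], by = 7L)
  if (length(full) > length(week_start) || anyNA(sst)) {
    sst <- approx(as.numeric(week_start), sst, xout = as.numeric(full),
                  rule = 1)$y
    week_start <- full
    if (anyNA(sst)) stop_rp("could not interpolate SST gaps for %s", site_id)
  }
  structure(list(site_id = site_id, week_start = week_start, sst = sst,
                 baseline = as.integer(baseline)),
            class = "sst_series")
}

#' @export
print.sst_series <- function(x, ...) {
  cat(sprintf("<sst_series> %s: %d weeks, %s to %s, baseline %d-%d\n",
              x$site_id, length(x$sst), format(x$week_start[1]),
              format(x$week_start[length(x$week_start)]),
              x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Read weekly SST series from delimited text
#'
#' Expects columns `site_id, week_start, sst_c`; one file may hold many
#' sites.
#'
#' @param path File path.
#' @param baseline Climatology baseline years passed to [sst_series()].
#' @param sep Field separator (`NULL` auto-detects).
#' @return A named list of `sst_series`, one per site.
#' @export
read_sst_series <- function(path, baseline = c(1985L, 2009L), sep = NULL) {
  df <- read_rp_table(path, sep = sep)
  assert_cols(df, c("site_id", "week_start", "sst_c"), "SST table")
  lapply(split(df, df$site_id), function(d) {
    sst_series(d$site_id[1], d$week_start, d$sst_c, baseline = baseline)
  })
}

#' Write a list of SST series to delimited text
#' @param series List of `sst_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sst_series <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(site_id = s$site_id, week_start = format(s$week_start),
               sst_c = s$sst)
  }))
  write_rp_table(df, path)
}

series_years <- function(s) as.integer(format(s$week_start, "%Y"))
series_months <- function(s) as.integer(format(s$week_start, "%m"))

in_baseline <- function(s) {
  yr <- series_years(s)
  yr >= s$baseline[1] & yr <= s$baseline[2]
}

#' Monthly climatology and maximum monthly mean (MMM)
#'
#' Assigns each baseline week to its calendar month, averages SST per month
#' over the whole baseline window, and takes the warmest month as the MMM —
#' the bleaching threshold reference temperature.
#'
#' @param s An `sst_series`.
#' @param min_years Minimum number of complete baseline years required
#'   (default 2).
#' @return List with `monthly_means` (12 values, degrees C) and `MMM`.
#' @export
monthly_climatology_mmm <- function(s, min_years = 2L) {
  base <- in_baseline(s)
  yrs <- unique(series_years(s)[base])
  complete <- vapply(yrs, function(y) {
    sum(series_years(s) == y & base) >= 48L
  }, logical(1))
  if (sum(complete) < min_years) {
    stop_rp("climatology baseline needs >= %d complete years, found %d",
            min_years, sum(complete))
  }
  mon <- series_months(s)[base]
  mm <- vapply(1:12, function(m) mean(s$sst[base][mon == m]), numeric(1))
  list(monthly_means = setNames(mm, month.abb), MMM = max(mm))
}

#' Degree heating weeks (DHW) from weekly SST
#'
#' The weekly HotSpot is the positive SST anomaly above the MMM. DHW at week
#' t is the sum, over the trailing `window` weeks including t, of HotSpots
#' at or above `hotspot_min` degrees C; smaller anomalies do not accumulate.
#' The first `window - 1` weeks are computed over the available partial
#' window.
#'
#' @param s An `sst_series`.
#' @param mmm Maximum monthly mean in degrees C (see
#'   [monthly_climatology_mmm()]).
#' @param window Accumulation window in weeks (default 12, i.e. 84 days).
#' @param hotspot_min Minimum HotSpot magnitude that accumulates (default
#'   1 degree C).
#' @return Numeric vector of DHW in degree C-weeks, aligned with
#'   `s$week_start`.
#' @export
dhw_series <- function(s, mmm, window = 12L, hotspot_min = 1) {
  if (!is.finite(mmm)) stop_rp("MMM must be finite")
  hs <- pmax(0, s$sst - mmm)
  hs[hs < hotspot_min] <- 0
  n <- length(hs)
  # direct window sums: immune to the cumulative rounding drift a
  # cumsum-difference scheme would introduce on long series
  vapply(seq_len(n), function(t) {
    sum(hs[max(1L, t - window + 1L):t])
  }, numeric(1))
}

#' Event-window heat stress metrics
#'
#' @param s An `sst_series`.
#' @param dhw DHW series aligned with `s` (see [dhw_series()]).
#' @param window Two dates (coercible with `as.Date`) delimiting the event,
#'   inclusive.
#' @return List with `MaxSST_event`, `MaxDHW_event`, `WkDHW4`, `WkDHW8`
#'   (weeks with DHW strictly above 4 / 8 degree C-weeks), `weeks_alert1`
#'   (weeks with DHW >= 4, the Alert Level I duration) and `event_window`.
#' @export
event_stress_metrics <- function(s, dhw, window) {
  window <- as.Date(window)
  idx <- s$week_start >= window[1] & s$week_start <= window[2]
  if (!any(idx)) stop_rp("event window contains no weeks of the series")
  list(MaxSST_event = max(s$sst[idx]),
       MaxDHW_event = max(dhw[idx]),
       WkDHW4 = sum(dhw[idx] > 4),
       WkDHW8 = sum(dhw[idx] > 8),
       weeks_alert1 = sum(dhw[idx] >= 4),
       event_window = window)
}

#' Historical climate-variability metrics over the baseline window
#'
#' Computes, over the climatology baseline years: the coefficient of
#' variation of weekly SST (`CV_SST`); the standard deviation across years
#' of the annual maximum weekly SST (`sigma_wk`) and of the annual maximum
#' monthly-mean SST (`sigma_mon`); the mean annual maximum weekly SST
#' (`MaxSST_avg`); the MMM; the mean annual maximum DHW (`MaxDHW_avg`); the
#' mean annual number of weeks with DHW above 4 and 8 degree C-weeks
#' (`WkDHW4_avg`, `WkDHW8_avg`); and the fraction of baseline years whose
#' annual maximum DHW exceeds 4 and 8 (`fDHW4`, `fDHW8`). Standard
#' deviations are sample (n - 1) standard deviations; years are calendar
#' years of the week-start dates.
#'
#' @param s An `sst_series`.
#' @param min_years Minimum number of baseline years (default 5).
#' @param window,hotspot_min DHW accumulation parameters (see
#'   [dhw_series()]).
#' @return Named list of the metrics above.
#' @export
historical_climate_metrics <- function(s, min_years = 5L, window = 12L,
                                       hotspot_min = 1) {
  base <- in_baseline(s)
  yr <- series_years(s)
  yrs <- sort(unique(yr[base]))
  if (length(yrs) < min_years) {
    stop_rp("historical metrics need >= %d baseline years, found %d",
            min_years, length(yrs))
  }
  clim <- monthly_climatology_mmm(s, min_years = min(2L, min_years))
  dhw <- dhw_series(s, clim$MMM, window = window, hotspot_min = hotspot_min)
  mon <- series_months(s)

  ann_max_wk <- vapply(yrs, function(y) max(s$sst[base & yr == y]),
                       numeric(1))
  ann_max_mon <- vapply(yrs, function(y) {
    mm <- tapply(s$sst[base & yr == y], mon[base & yr == y], mean)
    max(mm)
  }, numeric(1))
  ann_max_dhw <- vapply(yrs, function(y) max(dhw[base & yr == y]),
                        numeric(1))
  ann_wk4 <- vapply(yrs, function(y) sum(dhw[base & yr == y] > 4),
                    numeric(1))
  ann_wk8 <- vapply(yrs, function(y) sum(dhw[base & yr == y] > 8),
                    numeric(1))

  list(CV_SST = sd(s$sst[base]) / mean(s$sst[base]),
       sigma_wk = sd(ann_max_wk),
       sigma_mon = sd(ann_max_mon),
       MaxSST_avg = mean(ann_max_wk),
       MMM = clim$MMM,
       MaxDHW_avg = mean(ann_max_dhw),
       WkDHW4_avg = mean(ann_wk4),
       WkDHW8_avg = mean(ann_wk8),
       fDHW4 = mean(ann_max_dhw > 4),
       fDHW8 = mean(ann_max_dhw > 8))
}

#' Per-site climate metric table
#'
#' Convenience wrapper computing event and historical metrics for a list of
#' SST series and returning one row per site.
#'
#' @param series Named list of `sst_series` (see [read_sst_series()]).
#' @param event_window Two dates delimiting the heat-stress event.
#' @param ... Passed to [historical_climate_metrics()].
#' @return A data.frame with one row per site and all metric columns.
#' @export
climate_metric_table <- function(series, event_window, ...) {
  rows <- lapply(series, function(s) {
    clim <- monthly_climatology_mmm(s)
    dhw <- dhw_series(s, clim$MMM)
    ev <- event_stress_metrics(s, dhw, event_window)
    hist <- historical_climate_metrics(s, ...)
    data.frame(site_id = s$site_id,
               MaxSST_event = ev$MaxSST_event, MaxDHW_event = ev$MaxDHW_event,
               WkDHW4 = ev$WkDHW4, WkDHW8 = ev$WkDHW8,
               weeks_alert1 = ev$weeks_alert1,
               as.data.frame(hist), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
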
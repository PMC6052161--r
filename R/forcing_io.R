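#' Sensor time series
#'
#' A validated, uniform-interval scalar time series from one logging sensor.
#' Stored as a data frame with columns `timestamp` (POSIXct, continuous local
#' clock time, no DST shifts) and `value`, plus attributes recording the
#' variable and the nominal sampling interval. Timestamps must be strictly
#' increasing; spacings must be whole multiples of the interval (to 1 s), and
#' any spacing larger than one interval is recorded as a gap in the
#' `"gap_after"` attribute (row indices after which a gap occurs).
#'
#' Value ranges enforced per variable: DO, PAR, wind and CO2 are non-negative;
#' temperature must exceed -5 degrees C.
#'
#' @param variable One of `"DO"`, `"temperature"`, `"PAR"`, `"wind"`, `"CO2"`.
#'   Units: g O2 m^-3, degrees C, umol m^-2 s^-1, m s^-1, umol L^-1.
#' @param timestamps POSIXct vector, strictly increasing.
#' @param values Numeric vector, same length as `timestamps`.
#' @param interval Nominal spacing in minutes (default 10).
#' @return An object of class `sensor_series` (also a data frame).
#' @export
sensor_series <- function(variable, timestamps, values, interval = 10) {
  variable <- match.arg(variable, c("DO", "temperature", "PAR", "wind", "CO2"))
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct", call. = FALSE)
  }
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have equal length", call. = FALSE)
  }
  if (length(timestamps) == 0) stop("empty series", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  d <- as.numeric(diff(timestamps), units = "secs")
  if (any(d <= 0)) {
    bad <- format(timestamps[which(d <= 0) + 1L])
    stop("timestamps must be strictly increasing; offending timestamp(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  step <- interval * 60
  mult <- d / step
  if (any(abs(mult - round(mult)) * step > 1)) {
    bad <- format(timestamps[which(abs(mult - round(mult)) * step > 1) + 1L])
    stop("spacing must be a whole multiple of the ", interval,
         "-minute interval (1 s tolerance); offending timestamp(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  lo <- switch(variable, temperature = -5, 0)
  if (any(values < lo)) {
    stop(variable, " values must be >= ", lo, call. = FALSE)
  }
  structure(
    data.frame(timestamp = timestamps, value = values),
    variable = variable,
    interval = interval,
    gap_after = which(round(mult) > 1L),
    class = c("sensor_series", "data.frame")
  )
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %s: %d points at %g min, %s .. %s\n",
              attr(x, "variable"), nrow(x), attr(x, "interval"),
              format(x$timestamp[1]), format(x$timestamp[nrow(x)])))
  if (length(attr(x, "gap_after"))) {
    cat("  gaps after", length(attr(x, "gap_after")), "row(s)\n")
  }
  invisible(x)
}

#' Canonical CSV dialect for sensor files
#'
#' @param timestamp_col,value_col Column names holding the timestamp and value.
#' @param time_format `strptime` format of the timestamp column.
#' @return A list describing the dialect, passed to [read_sensor_csv()].
#' @export
sensor_dialect <- function(timestamp_col = "timestamp", value_col = "value",
                           time_format = "%Y-%m-%d %H:%M:%S") {
  list(timestamp_col = timestamp_col, value_col = value_col,
       time_format = time_format)
}

#' Read a sensor CSV file
#'
#' Reads a two-column delimited file into a [sensor_series()]. Rows whose
#' timestamp or value fail to parse are reported in the error, never silently
#' dropped; duplicated or out-of-order timestamps raise a validation error
#' naming the offending timestamps.
#'
#' @param path Path to the CSV file.
#' @param variable Variable name, as in [sensor_series()].
#' @param dialect Column/format description from [sensor_dialect()].
#' @param interval Nominal spacing in minutes.
#' @return A `sensor_series`.
#' @export
read_sensor_csv <- function(path, variable, dialect = sensor_dialect(),
                            interval = 10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c(dialect$timestamp_col, dialect$value_col)
  if (!all(need %in% names(raw))) {
    stop("format error: ", path, " lacks column(s) ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(raw[[dialect$timestamp_col]],
                   format = dialect$time_format, tz = "UTC")
  vals <- suppressWarnings(as.numeric(raw[[dialect$value_col]]))
  bad <- which(is.na(ts) | is.na(vals))
  if (length(bad)) {
    stop("unparseable row(s) in ", path, ": ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  sensor_series(variable, ts, vals, interval = interval)
}

#' Write a sensor series to the canonical CSV dialect
#'
#' Writes `timestamp,value` rows with ISO timestamps and 10 significant digits,
#' so that write -> read -> write is byte-stable.
#'
#' @param series A [sensor_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(series, path) {
  stopifnot(inherits(series, "sensor_series"))
  lines <- c("timestamp,value",
             sprintf("%s,%.10g",
                     format(series$timestamp, "%Y-%m-%d %H:%M:%S"),
                     series$value))
  writeLines(lines, path)
  invisible(path)
}

#' Daily mean of a sensor series
#'
#' Arithmetic mean of all observations falling on one calendar day, with the
#' number of contributing points. A full day at 10-minute spacing contributes
#' 144 points; partial days report their actual count.
#'
#' @param series A [sensor_series()].
#' @param date A `Date` (or string coercible to one).
#' @return A list with elements `value` (the mean) and `n` (points used).
#' @export
daily_mean <- function(series, date) {
  stopifnot(inherits(series, "sensor_series"))
  date <- as.Date(date)
  sel <- as.Date(series$timestamp, tz = "UTC") == date
  if (!any(sel)) {
    stop(errorCondition(
      paste0("no observations on ", format(date)),
      class = c("pondmetab_missing_day", "error", "condition")))
  }
  list(value = mean(series$value[sel]), n = sum(sel))
}

#' Daily means for every day covered by a series
#'
#' @param series A [sensor_series()].
#' @return A data frame with columns `date`, `value`, `n`.
#' @export
daily_means <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  day <- as.Date(series$timestamp, tz = "UTC")
  agg <- tapply(series$value, day, mean)
  n <- tapply(series$value, day, length)
  data.frame(date = as.Date(names(agg)), value = as.numeric(agg),
             n = as.integer(n), row.names = NULL)
}

#' Validate a table of daily drivers
#'
#' Daily drivers are the slowly varying inputs of the diel oxygen model: the
#' mixing depth `zmix` (m), the fraction of pond area open to the atmosphere
#' (`open_fraction`, 0 under full ice to 1 ice-free) and, optionally, the ice
#' thickness (m).
#'
#' @param daily Data frame with columns `date`, `zmix`, `open_fraction` and
#'   optionally `ice_thickness`.
#' @param total_depth Optional water-column depth (m); `zmix` may not exceed it.
#' @return The validated data frame (dates coerced to `Date`).
#' @export
validate_daily_drivers <- function(daily, total_depth = NULL) {
  need <- c("date", "zmix", "open_fraction")
  if (!all(need %in% names(daily))) {
    stop("daily drivers need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  daily$date <- as.Date(daily$date)
  if (any(daily$zmix <= 0)) stop("zmix must be > 0", call. = FALSE)
  if (!is.null(total_depth) && any(daily$zmix > total_depth + 1e-9)) {
    stop("zmix may not exceed the water-column depth", call. = FALSE)
  }
  if (any(daily$open_fraction < 0 | daily$open_fraction > 1)) {
    stop("open_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(daily$ice_thickness) && any(daily$ice_thickness < 0)) {
    stop("ice_thickness must be >= 0", call. = FALSE)
  }
  daily
}

#' Read per-pond daily drivers / pond manifest
#'
#' `read_daily_drivers()` expects columns `date,zmix,open_fraction` and
#' optionally `ice_thickness` (plus an optional `pond_id`);
#' `read_pond_manifest()` expects `pond_id,group` with group `control` or
#' `treatment`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_daily_drivers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_daily_drivers(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_daily_drivers
#' @export
read_pond_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pond_id", "group") %in% names(m))) {
    stop("manifest needs columns pond_id, group", call. = FALSE)
  }
  if (!all(m$group %in% c("control", "treatment"))) {
    stop("group must be 'control' or 'treatment'", call. = FALSE)
  }
  m
}

#' Align sensor series onto a common model grid
#'
#' Interpolates a set of sensor series onto one uniform grid (anchored at the
#' DO series, which defines the model's time step), restricted to the window
#' covered by every series. Grid points that do not coincide with a source
#' observation (offset series, points inside a gap) are linearly interpolated
#' and flagged; a gap longer than `max_gap` minutes is an alignment error
#' (such pond-days are not fit).
#'
#' @param series_list Named list of [sensor_series()]; must contain `DO` and
#'   may contain `PAR`, `temperature`, `wind`.
#' @param daily Daily driver table (see [validate_daily_drivers()]); must cover
#'   every calendar day of the aligned grid.
#' @param pond_id,group Pond identity carried through to the result.
#' @param delta_t_minutes Grid spacing in minutes.
#' @param max_gap Longest tolerated source gap, minutes.
#' @return An object of class `pond_forcing`: list with `pond_id`, `group`,
#'   `time` (grid), `data` (data frame of interpolated variables),
#'   `interpolated` (logical matrix flagging gap-filled points), `daily`,
#'   `delta_t` (days).
#' @export
align_forcing <- function(series_list, daily, pond_id = "pond", group = "control",
                          delta_t_minutes = 10, max_gap = 30) {
  if (!"DO" %in% names(series_list)) {
    stop("`series_list` must contain a 'DO' series", call. = FALSE)
  }
  daily <- validate_daily_drivers(daily)
  starts <- vapply(series_list, function(s) as.numeric(s$timestamp[1]), 0)
  ends <- vapply(series_list, function(s) as.numeric(s$timestamp[nrow(s)]), 0)
  do_ts <- as.numeric(series_list$DO$timestamp)
  keep <- do_ts >= max(starts) - 1 & do_ts <= min(ends) + 1
  if (!any(keep)) stop("series have no overlapping coverage", call. = FALSE)
  step <- delta_t_minutes * 60
  t0 <- do_ts[keep][1]
  grid <- seq(t0, do_ts[keep][sum(keep)], by = step)
  out <- data.frame(row.names = seq_along(grid))
  flags <- matrix(FALSE, length(grid), length(series_list),
                  dimnames = list(NULL, names(series_list)))
  for (nm in names(series_list)) {
    s <- series_list[[nm]]
    ts <- as.numeric(s$timestamp)
    out[[nm]] <- stats::approx(ts, s$value, xout = grid, rule = 2)$y
    left <- findInterval(grid, ts)
    inside <- left >= 1 & left < length(ts)
    gapw <- rep(0, length(grid))
    gapw[inside] <- ts[left[inside] + 1L] - ts[left[inside]]
    on_obs <- abs(grid - ts[pmax(left, 1L)]) <= 1 |
      abs(grid - ts[pmin(pmax(left, 1L) + 1L, length(ts))]) <= 1
    bridged <- inside & !on_obs & gapw > max_gap * 60 + 1
    if (any(bridged)) {
      i <- which(bridged)[1]
      stop("alignment error: gap in ", nm, " exceeding ", max_gap,
           " min spanning ",
           format(as.POSIXct(ts[left[i]], tz = "UTC", origin = "1970-01-01")),
           " .. ",
           format(as.POSIXct(ts[left[i] + 1L], tz = "UTC",
                             origin = "1970-01-01")),
           call. = FALSE)
    }
    flags[, nm] <- !on_obs
  }
  time <- as.POSIXct(grid, tz = "UTC", origin = "1970-01-01")
  grid_days <- unique(as.Date(time, tz = "UTC"))
  missing <- setdiff(format(grid_days), format(daily$date))
  if (length(missing)) {
    stop("no daily driver record for day(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(pond_id = pond_id, group = group, time = time, data = out,
         interpolated = flags, daily = daily,
         delta_t = delta_t_minutes / 1440),
    class = "pond_forcing"
  )
}

#' @export
print.pond_forcing <- function(x, ...) {
  cat(sprintf("<pond_forcing> %s (%s): %d grid points (dt = %.5f d), %d day(s)\n",
              x$pond_id, x$group, nrow(x$data), x$delta_t, nrow(x$daily)))
  invisible(x)
}

#' Write the aligned grid as one tidy CSV
#'
#' @param forcing A `pond_forcing` from [align_forcing()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "pond_forcing"))
  df <- cbind(
    data.frame(pond_id = forcing$pond_id,
               timestamp = format(forcing$time, "%Y-%m-%d %H:%M:%S")),
    forcing$data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
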
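#' Serial day numbers
#'
#' Wall-clock timestamps are reconciled with elapsed device times through a
#' serial day number: fractional days elapsed since January 1 of year 0 in
#' the proleptic Gregorian calendar (the convention of numeric date stacks
#' such as MATLAB's `datenum`, where 0000-01-01 00:00 is day 1). Only
#' differences and round trips are observable downstream; both are exact to
#' well under 1 ms for any modern timestamp.
#'
#' `serial_day_number()` accepts `POSIXct` (used as civil time; the timezone
#' field is ignored) or a `"%Y-%m-%d %H:%M:%S"` string.
#' `serial_to_timestamp()` is its inverse.
#'
#' @param timestamp A `POSIXct` or a `"%Y-%m-%d %H:%M:%S"` string.
#' @return `serial_day_number()`: numeric days; `serial_to_timestamp()`: a
#'   UTC `POSIXct`.
#' @export
#' @examples
#' serial_day_number("2012-03-01 14:30:00")
#' serial_to_timestamp(serial_day_number("2012-03-01 14:30:00"))
serial_day_number <- function(timestamp) {
  p <- parse_wallclock(timestamp)
  days_from_civil(p$year, p$month, p$day) + 719529 +
    (p$hour * 3600 + p$min * 3600 / 60 + p$sec) / 86400
}

#' @rdname serial_day_number
#' @param sdn Numeric serial day number(s).
#' @export
serial_to_timestamp <- function(sdn) {
  days <- floor(sdn + 1e-9 / 86400)
  secs <- round((sdn - days) * 86400 * 1000) / 1000
  civ <- civil_from_days(days - 719529)
  out <- ISOdatetime(civ$year, civ$month, civ$day, 0, 0, 0, tz = "UTC") + secs
  out
}

# Proleptic-Gregorian civil-date <-> day-count arithmetic (days relative to
# the Unix epoch 1970-01-01), written out directly so the serial-day routine
# does not depend on platform time facilities.
days_from_civil <- function(y, m, d) {
  y <- ifelse(m <= 2, y - 1, y)
  era <- floor(y / 400)
  yoe <- y - era * 400
  doy <- floor((153 * (m + ifelse(m > 2, -3, 9)) + 2) / 5) + d - 1
  doe <- yoe * 365 + floor(yoe / 4) - floor(yoe / 100) + doy
  era * 146097 + doe - 719468
}

civil_from_days <- function(z) {
  z <- z + 719468
  era <- floor(z / 146097)
  doe <- z - era * 146097
  yoe <- floor((doe - floor(doe / 1460) + floor(doe / 36524) -
    floor(doe / 146096)) / 365)
  y <- yoe + era * 400
  doy <- doe - (365 * yoe + floor(yoe / 4) - floor(yoe / 100))
  mp <- floor((5 * doy + 2) / 153)
  d <- doy - floor((153 * mp + 2) / 5) + 1
  m <- mp + ifelse(mp < 10, 3, -9)
  list(year = ifelse(m <= 2, y + 1, y), month = m, day = d)
}

parse_wallclock <- function(timestamp) {
  if (inherits(timestamp, "POSIXct")) {
    lt <- as.POSIXlt(timestamp, tz = attr(timestamp, "tzone") %||% "UTC")
    return(list(
      year = lt$year + 1900, month = lt$mon + 1, day = lt$mday,
      hour = lt$hour, min = lt$min, sec = lt$sec
    ))
  }
  m <- regmatches(
    timestamp,
    regexec("^(\\d{1,4})-(\\d{1,2})-(\\d{1,2})[ T](\\d{1,2}):(\\d{1,2}):(\\d{1,2}(\\.\\d+)?)$",
      timestamp
    )
  )[[1L]]
  if (length(m) == 0L) {
    abort(paste0("cannot parse timestamp: ", timestamp))
  }
  v <- as.numeric(m[2:7])
  if (v[2] < 1 || v[2] > 12 || v[3] < 1 || v[3] > 31 ||
      v[4] > 23 || v[5] > 59 || v[6] >= 61) {
    abort(paste0("invalid calendar fields in timestamp: ", timestamp))
  }
  list(year = v[1], month = v[2], day = v[3], hour = v[4], min = v[5], sec = v[6])
}

# ---- clock triplets -------------------------------------------------------

#' Clock triplets and sentinel codes
#'
#' Registry time variables are stored as hour/minute/second integer triplets.
#' Besides valid times of day, three sentinel triplets are in use:
#' `99:99:99` (unknown, or persistent VF for the VF-onset variable),
#' `88:88:88` (no CPR administered / no onset found) and `66:66:66`
#' (no data available). The literals `00:00:00` and `12:00:00` are
#' classified `suspect_literal` only when the manual source flags them as
#' placeholder edits.
#'
#' `clock_triplet()` builds a triplet tibble; `triplet_sentinel()` returns
#' one of the sentinel triplets; `classify_triplet()` maps every triplet to
#' exactly one class.
#'
#' @param hr,mn,sc Integer vectors (recycled to a common length).
#' @return `clock_triplet()`: a tibble with `hr`, `mn`, `sc`;
#'   `classify_triplet()`: character vector in
#'   `valid`, `unknown_99`, `no_cpr_88`, `no_data_66`, `suspect_literal`.
#' @export
#' @examples
#' classify_triplet(clock_triplet(99, 99, 99))
#' classify_triplet(clock_triplet(14, 33, 18))
clock_triplet <- function(hr, mn, sc) {
  tibble(hr = as.integer(hr), mn = as.integer(mn), sc = as.integer(sc))
}

#' @rdname clock_triplet
#' @param kind `"unknown"`, `"no_cpr"` or `"no_data"`.
#' @export
triplet_sentinel <- function(kind = c("unknown", "no_cpr", "no_data")) {
  kind <- match.arg(kind)
  v <- switch(kind, unknown = 99L, no_cpr = 88L, no_data = 66L)
  clock_triplet(v, v, v)
}

#' @rdname clock_triplet
#' @param t A triplet tibble (columns `hr`, `mn`, `sc`).
#' @param flagged Logical vector: does the manual source mark this value as a
#'   placeholder edit? Controls the `suspect_literal` class for `00:00:00`
#'   and `12:00:00`.
#' @export
classify_triplet <- function(t, flagged = FALSE) {
  flagged <- rep_len(flagged, nrow(t))
  out <- rep(NA_character_, nrow(t))
  sent <- function(v) t$hr == v & t$mn == v & t$sc == v
  out[sent(99L)] <- "unknown_99"
  out[sent(88L)] <- "no_cpr_88"
  out[sent(66L)] <- "no_data_66"
  open <- is.na(out)
  valid <- open & t$hr >= 0L & t$hr <= 23L & t$mn >= 0L & t$mn <= 59L &
    t$sc >= 0L & t$sc <= 59L
  literal <- valid & flagged &
    ((t$hr == 0L & t$mn == 0L & t$sc == 0L) |
      (t$hr == 12L & t$mn == 0L & t$sc == 0L))
  out[valid] <- "valid"
  out[literal] <- "suspect_literal"
  if (anyNA(out)) {
    i <- which(is.na(out))[1L]
    abort(sprintf(
      "malformed clock triplet %02d:%02d:%02d (out of range, not a sentinel)",
      t$hr[i], t$mn[i], t$sc[i]
    ))
  }
  out
}

#' Convert an elapsed time to a wall-clock triplet
#'
#' Adds `elapsed` seconds to the device power-on timestamp, rounds half-up to
#' the nearest whole second (the registry stores whole seconds), and returns
#' the time-of-day triplet. Day rollover is handled; the date survives in the
#' serial day number but only the time of day is reported, as in the
#' registry sheets. An unknown power-on time propagates the `99:99:99`
#' sentinel.
#'
#' @param elapsed Numeric seconds since power-on (vectorized).
#' @param power_on Power-on timestamp (`POSIXct` or string), or `NA` if
#'   unknown.
#' @return A triplet tibble (one row per element of `elapsed`).
#' @export
#' @examples
#' elapsed_to_clock(198, "2012-03-01 14:30:00")
elapsed_to_clock <- function(elapsed, power_on) {
  n <- length(elapsed)
  if (length(power_on) != 1L || is.na(power_on[[1L]])) {
    out <- triplet_sentinel("unknown")[rep(1L, n), ]
    attr(out, "note") <- "power-on time unknown; sentinel propagated"
    return(out)
  }
  base <- serial_day_number(power_on)
  # round half-up on total seconds, then split into time of day
  tot <- floor(base * 86400 + elapsed + 0.5)
  sod <- tot %% 86400
  clock_triplet(sod %/% 3600, (sod %% 3600) %/% 60, sod %% 60)
}

# Seconds-of-day of a triplet (valid triplets only).
triplet_seconds <- function(t) {
  t$hr * 3600L + t$mn * 60L + t$sc
}
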
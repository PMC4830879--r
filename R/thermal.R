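# Thermal development model: accumulated degree hours (ADH) over arbitrary
# temperature histories, conversion between ADH, development proportion and
# chronological time, and the inverse (age) problem.
#
# ADH is accumulated above a lower developmental threshold (1 C for the
# London C. vicina population the calibration derives from). Because the total
# ADH requirement is itself temperature dependent (756 ADH at 7.3 C vs 384 ADH
# at 25 C), development over fluctuating profiles uses rate summation: each
# time step contributes dt * (T - base) / ADH_total(T), with ADH_total linear
# in temperature between the two calibrated points.

#' Construct a temperature profile
#'
#' A temperature history as a piecewise-constant (left-hold) time series:
#' the temperature at time `t` is the value at the latest sample time not
#' after `t`, matching data-logger semantics. The last sample extends
#' indefinitely to the right.
#'
#' @param time_h Sample times in hours on a continuous axis; strictly
#'   increasing.
#' @param temp_c Temperatures in degrees Celsius, one per sample time.
#' @return An object of class `temperature_profile`.
#' @examples
#' temperature_profile(c(0, 10), c(7.3, 25))
#' @export
temperature_profile <- function(time_h, temp_c) {
  if (length(time_h) == 0) stop_input("temperature profile needs at least one sample")
  if (length(time_h) != length(temp_c)) {
    stop_input("time_h and temp_c must have equal length")
  }
  if (!all(is.finite(time_h)) || !all(is.finite(temp_c))) {
    stop_input("temperature profile samples must be finite")
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop_input("timestamps must be strictly increasing")
  }
  structure(list(time_h = as.numeric(time_h), temp_c = as.numeric(temp_c)),
            class = "temperature_profile")
}

#' Constant temperature profile
#'
#' @param temp_c Constant temperature in degrees Celsius.
#' @param t_start Time at which the profile starts, in hours.
#' @return A `temperature_profile` holding `temp_c` from `t_start` onwards.
#' @export
constant_profile <- function(temp_c, t_start = 0) {
  temperature_profile(t_start, temp_c)
}

#' @export
print.temperature_profile <- function(x, ...) {
  n <- length(x$time_h)
  cat(sprintf("Temperature profile: %d sample(s), %g h onwards, %g..%g C\n",
              n, x$time_h[1], min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

# Temperature at time t under left-hold; t before the first sample takes the
# first sample's value (callers decide whether clamping warrants a warning).
.temp_at <- function(profile, t) {
  idx <- findInterval(t, profile$time_h)
  idx[idx == 0L] <- 1L
  profile$temp_c[idx]
}

# Split [t_start, t_end] at the profile's interior sample times.
.segments <- function(profile, t_start, t_end) {
  tt <- profile$time_h
  inner <- tt[tt > t_start & tt < t_end]
  knots <- c(t_start, inner, t_end)
  list(t0 = knots[-length(knots)], t1 = knots[-1])
}

#' Accumulate degree hours over a temperature history
#'
#' Evaluates `integral of max(0, T(t) - base) dt` exactly under the profile's
#' piecewise-constant interpolation. The result is additive over sub-intervals.
#'
#' @param profile A [temperature_profile()].
#' @param t_start,t_end Integration bounds in hours, `t_start <= t_end`. A
#'   `t_start` before the profile's first sample is clamped to it, with a
#'   warning recorded on the ledger.
#' @param base_temp_c Lower developmental threshold in degrees Celsius
#'   (default 1).
#' @return An object of class `adh_ledger`: list with `t_start`, `t_end`,
#'   `base_temp_c`, `adh` (the accumulated degree hours) and `per_step`
#'   (data frame of per-segment contributions), plus a `warnings` character
#'   vector.
#' @examples
#' accumulate_adh(constant_profile(7.3), 0, 12)$adh   # 75.6
#' @export
accumulate_adh <- function(profile, t_start, t_end, base_temp_c = 1) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (!is_scalar_number(t_start) || !is_scalar_number(t_end)) {
    stop_input("t_start and t_end must be finite numbers")
  }
  if (t_start > t_end) stop_input("reversed interval: t_start > t_end")
  warnings <- character(0)
  if (t_start < profile$time_h[1]) {
    warnings <- c(warnings, sprintf(
      "t_start %g h precedes profile start %g h; clamped", t_start,
      profile$time_h[1]))
    t_start <- profile$time_h[1]
    t_end <- max(t_end, t_start)
  }
  seg <- .segments(profile, t_start, t_end)
  dt <- seg$t1 - seg$t0
  temp <- .temp_at(profile, seg$t0)
  contrib <- pmax(0, temp - base_temp_c) * dt
  keep <- dt > 0
  structure(
    list(
      t_start = t_start, t_end = t_end, base_temp_c = base_temp_c,
      adh = sum(contrib),
      per_step = data.frame(t0 = seg$t0[keep], t1 = seg$t1[keep],
                            dt = dt[keep], temp_c = temp[keep],
                            contribution = contrib[keep]),
      warnings = warnings
    ),
    class = "adh_ledger"
  )
}

#' @export
print.adh_ledger <- function(x, ...) {
  cat(sprintf("ADH ledger: %.4g degree-hours over [%g, %g] h (base %g C, %d step(s))\n",
              x$adh, x$t_start, x$t_end, x$base_temp_c, nrow(x$per_step)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Common base threshold of a staging table's calibration.
.table_base <- function(table) {
  b <- unique(table$temperatures$base_temp_c)
  if (length(b) != 1) stop_input("calibration has inconsistent base thresholds")
  b
}

#' ADH required to reach a development proportion
#'
#' At a calibrated temperature the requirement is
#' `proportion * (temp - base) * total_duration_h`, reproducing the printed
#' per-interval ADH milestones. Between the calibrated temperatures the
#' requirement is interpolated linearly in temperature at fixed proportion;
#' outside the calibrated range it is clamped to the nearest calibrated
#' temperature and an extrapolation warning is attached (attribute
#' `"extrapolation_warning"`).
#'
#' @param proportion Development fraction(s) in `[0, 1]`.
#' @param temp_c Effective temperature in degrees Celsius.
#' @param table A `staging_table` carrying the calibration.
#' @return Numeric vector of degree-hours, same length as `proportion`.
#' @examples
#' tab <- load_staging_table()
#' adh_required(1.0, 7.3, tab)   # 756
#' adh_required(0.5, 25, tab)    # 192
#' @export
adh_required <- function(proportion, temp_c, table) {
  stopifnot(inherits(table, "staging_table"))
  if (!is.numeric(proportion) || any(!is.finite(proportion)) ||
      any(proportion < 0 | proportion > 1)) {
    stop_input("proportion must lie in [0, 1]")
  }
  if (!is_scalar_number(temp_c)) stop_input("temp_c must be a finite number")
  cal <- table$temperatures
  totals <- (cal$temp_c - cal$base_temp_c) * cal$total_duration_h
  warn <- NULL
  t_eff <- temp_c
  if (temp_c < min(cal$temp_c)) {
    t_eff <- min(cal$temp_c)
    warn <- sprintf("temperature %g C below calibrated range [%g, %g]; requirement clamped to %g C",
                    temp_c, min(cal$temp_c), max(cal$temp_c), t_eff)
  } else if (temp_c > max(cal$temp_c)) {
    t_eff <- max(cal$temp_c)
    warn <- sprintf("temperature %g C above calibrated range [%g, %g]; requirement clamped to %g C",
                    temp_c, min(cal$temp_c), max(cal$temp_c), t_eff)
  }
  total_at_t <- if (nrow(cal) == 1) totals else {
    stats::approx(cal$temp_c, totals, xout = t_eff)$y
  }
  out <- proportion * total_at_t
  if (!is.null(warn)) attr(out, "extrapolation_warning") <- warn
  out
}

# Development rate (proportion per hour) at a constant temperature.
.dev_rate <- function(temp_c, table) {
  base <- .table_base(table)
  excess <- max(0, temp_c - base)
  if (excess == 0) return(0)
  req <- as.numeric(adh_required(1, temp_c, table))
  excess / req
}

#' Advance development over a temperature history
#'
#' Rate-summation integration of proportional development: each
#' piecewise-constant segment of the profile contributes
#' `dt * max(0, T - base) / adh_required(1, T)`. Development caps at 1.0
#' (hatching); the crossing time, if reached, is attached as attribute
#' `"hatch_time_h"`.
#'
#' @inheritParams accumulate_adh
#' @param table A `staging_table` carrying the calibration.
#' @return The development proportion reached (numeric in `[0, 1]`), with
#'   attribute `hatch_time_h` (`NA` if hatching was not reached).
#' @examples
#' tab <- load_staging_table()
#' advance_development(constant_profile(25), 0, 16, tab)   # 1.0
#' @export
advance_development <- function(profile, t_start, t_end, table) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (!is_scalar_number(t_start) || !is_scalar_number(t_end)) {
    stop_input("t_start and t_end must be finite numbers")
  }
  if (t_start > t_end) stop_input("reversed interval: t_start > t_end")
  t_start <- max(t_start, profile$time_h[1])
  t_end <- max(t_end, t_start)
  seg <- .segments(profile, t_start, t_end)
  p <- 0
  t_hatch <- NA_real_
  for (k in seq_along(seg$t0)) {
    dt <- seg$t1[k] - seg$t0[k]
    if (dt <= 0) next
    rate <- .dev_rate(.temp_at(profile, seg$t0[k]), table)
    if (rate <= 0) next
    dp <- rate * dt
    if (p + dp >= 1) {
      t_hatch <- seg$t0[k] + (1 - p) / rate
      p <- 1
      break
    }
    p <- p + dp
  }
  structure(p, hatch_time_h = t_hatch)
}

# Earliest time (profile axis) at which development from the profile start
# reaches proportion p; falls back to the profile end + one stalled doubling
# cap if p is unreachable (the caller's inversion then reports censoring).
.time_to_reach <- function(profile, p, table, tol = 0.01) {
  t0 <- profile$time_h[1]
  if (p <= 0) return(t0)
  dt <- 1
  for (k in 1:40) {
    if (as.numeric(advance_development(profile, t0, t0 + dt, table)) >= p) break
    dt <- dt * 2
  }
  hi <- t0 + dt
  lo <- t0
  if (as.numeric(advance_development(profile, t0, hi, table)) < p) return(hi)
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (as.numeric(advance_development(profile, t0, mid, table)) >= p - 1e-9) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}

#' Invert the thermal model: chronological age bounds from proportion bounds
#'
#' Finds elapsed times `t` (hours before `collection_time`) such that
#' development accumulated from `collection_time - t` to `collection_time`
#' reaches `p_lo` (lower age bound) and `p_hi` (upper age bound), by monotone
#' bisection to the stated tolerance. If a proportion is unreachable within
#' the profile's span the corresponding bound is censored at the profile
#' start.
#'
#' @param proportion_range Numeric `c(p_lo, p_hi)` with
#'   `0 <= p_lo <= p_hi <= 1`.
#' @param profile A [temperature_profile()] covering a window ending at
#'   `collection_time`.
#' @param collection_time Collection time in hours on the profile's axis.
#' @param table A `staging_table` carrying the calibration.
#' @param tol Root tolerance in hours (default 0.01).
#' @return An object of class `age_bounds`: list with `lower_h`, `upper_h`
#'   (hours before collection), `censored` (logical: was either bound cut off
#'   at the profile start), and `tol`.
#' @examples
#' tab <- load_staging_table()
#' invert_age(c(1, 1), constant_profile(7.3), 120, tab)$upper_h   # ~120
#' @export
invert_age <- function(proportion_range, profile, collection_time, table,
                       tol = 0.01) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (length(proportion_range) != 2 || any(!is.finite(proportion_range)) ||
      proportion_range[1] < 0 || proportion_range[2] > 1 ||
      proportion_range[1] > proportion_range[2]) {
    stop_input("proportion_range must be c(p_lo, p_hi) with 0 <= p_lo <= p_hi <= 1")
  }
  if (!is_scalar_number(collection_time)) {
    stop_input("collection_time must be a finite number")
  }
  span <- collection_time - profile$time_h[1]
  if (span < 0) stop_input("collection_time precedes the profile start")

  dev_at_age <- function(t) {
    as.numeric(advance_development(profile, collection_time - t,
                                   collection_time, table))
  }
  solve_one <- function(p) {
    if (p <= 0) return(list(t = 0, censored = FALSE))
    if (dev_at_age(span) < p - 1e-9) return(list(t = span, censored = TRUE))
    lo <- 0
    hi <- span
    while (hi - lo > tol / 2) {
      mid <- (lo + hi) / 2
      if (dev_at_age(mid) >= p - 1e-9) hi <- mid else lo <- mid
    }
    list(t = hi, censored = FALSE)
  }
  lo <- solve_one(proportion_range[1])
  hi <- solve_one(proportion_range[2])
  structure(
    list(lower_h = lo$t, upper_h = hi$t,
         censored = lo$censored || hi$censored, tol = tol),
    class = "age_bounds"
  )
}

#' @export
print.age_bounds <- function(x, ...) {
  cat(sprintf("Age bounds: %.2f to %.2f h before collection%s (tolerance %g h)\n",
              x$lower_h, x$upper_h,
              if (x$censored) " [censored at profile start]" else "", x$tol))
  invisible(x)
}

#' Read a temperature log
#'
#' Reads a CSV with header `timestamp,temp_c`. Timestamps may be decimal
#' hours or ISO 8601 date-times (auto-detected); ISO timestamps are converted
#' to hours elapsed since the first record. The detected dialect is recorded
#' as attribute `"dialect"`.
#'
#' @param path Path to the CSV log.
#' @return A [temperature_profile()].
#' @export
read_temperature_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df))) {
    stop_input("temperature log must have columns timestamp,temp_c")
  }
  hours <- suppressWarnings(as.numeric(df$timestamp))
  if (!anyNA(hours)) {
    dialect <- "decimal_hours"
  } else {
    ts <- as.POSIXct(df$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (anyNA(ts)) {
      stop_input("timestamps are neither decimal hours nor ISO 8601: ",
                 df$timestamp[which(is.na(ts))[1]])
    }
    hours <- as.numeric(difftime(ts, ts[1], units = "hours"))
    dialect <- "iso8601"
  }
  prof <- temperature_profile(hours, as.numeric(df$temp_c))
  attr(prof, "dialect") <- dialect
  prof
}
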
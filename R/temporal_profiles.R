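# Hourly contact-activity profiles: packet counts per hour of day,
# split weekday/weekend and by the status pair of the interacting
# individuals (patient-patient, staff-patient, staff-staff).

#' Hourly packet counts
#'
#' Counts raw 30-s packets per `(date, hour, pair_type)` over the study
#' period, dropping dates inside gap intervals and dates belonging to
#' excluded ISO weeks (e.g. the weeks containing battery changes). The
#' hour bin is `[h:00, h+1:00)`. The grid is complete: every retained
#' date contributes 24 x 4 rows, zero-filled, for pair types `all`,
#' `patient_patient`, `staff_patient` and `staff_staff`.
#'
#' @param records Canonical record table.
#' @param roster Roster (statuses define the pair type).
#' @param gaps Gap schedule.
#' @param origin Calendar date of day 0.
#' @param exclude_weeks Character vector of ISO week labels
#'   (`"2009-W31"`) to drop entirely.
#' @param distinct If `TRUE`, count distinct partners-pairs per hour
#'   instead of raw packets.
#' @return `data.table(date, hour, day_type, pair_type, n_records)`.
#' @export
hourly_counts <- function(records, roster, gaps = NULL,
                          origin = as.Date("2009-07-01"),
                          exclude_weeks = character(),
                          distinct = FALSE) {
  rec <- as.data.table(records)[, .(t, id_a, id_b)]
  ros <- as.data.table(roster)
  rec[, date := cpi_date(t, origin)]
  rec[, hour := (t %% DAY_S) %/% 3600L]
  keep_date <- function(d) !in_gap(d, gaps) & !(iso_week(d) %in% exclude_weeks)
  rec <- rec[keep_date(date)]
  status_of <- setNames(ros$status, ros$id)
  sa <- status_of[rec$id_a]
  sb <- status_of[rec$id_b]
  rec[, pair_type := fifelse(sa == "patient" & sb == "patient",
                             "patient_patient",
                      fifelse(sa == "staff" & sb == "staff",
                              "staff_staff", "staff_patient"))]
  rec <- rec[!is.na(pair_type)]
  if (nrow(rec)) {
    if (distinct) {
      sub <- rec[, .(n_records = uniqueN(paste(id_a, id_b))),
                 by = .(date, hour, pair_type)]
    } else {
      sub <- rec[, .(n_records = .N), by = .(date, hour, pair_type)]
    }
    all_rows <- sub[, .(n_records = sum(n_records)), by = .(date, hour)]
    all_rows[, pair_type := "all"]
    counts <- rbindlist(list(all_rows, sub), use.names = TRUE)
    dates <- sort(unique(rec$date))
  } else {
    counts <- data.table(date = as.Date(character()), hour = integer(),
                         pair_type = character(), n_records = integer())
    dates <- as.Date(character())
  }
  if (length(dates) == 0L) {
    return(data.table(date = as.Date(character()), hour = integer(),
                      day_type = character(), pair_type = character(),
                      n_records = integer()))
  }
  grid <- CJ(date = dates, hour = 0:23,
             pair_type = c("all", "patient_patient", "staff_patient",
                           "staff_staff"))
  out <- counts[grid, on = c("date", "hour", "pair_type")]
  out[is.na(n_records), n_records := 0L]
  out[, day_type := fifelse(is_weekend(date), "weekend", "weekday")]
  setcolorder(out, c("date", "hour", "day_type", "pair_type", "n_records"))
  setorder(out, date, hour, pair_type)
  out[]
}

#' Five-number summary of hourly counts per hour of day
#'
#' For one day type, summarizes the distribution over days of the `all`
#' pair-type hourly counts: minimum, lower quartile, median, upper
#' quartile and maximum per hour. Quantiles use the linear-interpolation
#' (type 7) convention.
#'
#' @param counts Output of [hourly_counts()].
#' @param day_type `"weekday"` or `"weekend"`.
#' @return `data.table(hour, min, q1, median, q3, max, n_days)`.
#' @export
hourly_distribution <- function(counts, day_type = c("weekday", "weekend")) {
  dtp <- match.arg(day_type)
  x <- as.data.table(counts)[day_type == dtp & pair_type == "all"]
  if (nrow(x) == 0L) {
    message("no ", dtp, " rows in counts")
    return(data.table(hour = integer(), min = numeric(), q1 = numeric(),
                      median = numeric(), q3 = numeric(), max = numeric(),
                      n_days = integer()))
  }
  x[, {
    q <- quantile(n_records, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    .(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
      n_days = .N)
  }, by = hour][order(hour)]
}

#' Median hourly counts by pair type
#'
#' Median over days of the hourly count, per pair type and hour of day;
#' the trace behind the "which pairs drive which hours" comparison
#' (patient-patient activity shows a much flatter night/day contrast
#' than staff-involved contact).
#'
#' @param counts Output of [hourly_counts()].
#' @return `data.table(pair_type, hour, median, n_days)`.
#' @export
median_hourly_by_pairtype <- function(counts) {
  x <- as.data.table(counts)[pair_type != "all"]
  x[, .(median = median(n_records), n_days = .N),
    by = .(pair_type, hour)][order(pair_type, hour)]
}

#' Cyclic smoother for 24-hour profiles
#'
#' Gaussian-kernel smoother on the circle of hours (hour 23 is adjacent
#' to hour 0). Kernel weights depend only on circular hour distance and
#' rows are normalized, so constants are preserved exactly and — the
#' smoothing matrix being doubly stochastic on the equispaced circular
#' grid — so is the series total. As `bandwidth` tends to 0 the output
#' converges to the input.
#'
#' @param x Numeric vector of 24 per-hour values.
#' @param bandwidth Kernel standard deviation in hours.
#' @return Smoothed numeric vector of 24 values.
#' @export
smooth_profile <- function(x, bandwidth = 1.5) {
  if (length(x) != 24L) stop("x must have 24 hourly values")
  if (bandwidth <= 0) return(x)
  h <- 0:23
  d <- outer(h, h, function(a, b) pmin(abs(a - b), 24 - abs(a - b)))
  w <- dnorm(d, sd = bandwidth)
  w <- w / rowSums(w)
  as.numeric(w %*% x)
}
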
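# Controlled vocabularies and small shared helpers.

#' Controlled vocabularies
#'
#' Category, ward, gender and hospitalization-reason labels accepted by
#' the readers and used throughout the package. `administration` and
#' `animation` are accepted on input so that a roster can carry them,
#' but the statistical analyses exclude those groups (their contact
#' involvement is negligible and they are filtered from outcome tables).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
CPI_CATEGORIES <- c("patient", "HCW", "reeducation", "AHS", "physician",
                    "hospital_porter", "logistic")

#' @rdname vocabularies
#' @export
CPI_EXTRA_CATEGORIES <- c("administration", "animation")

#' @rdname vocabularies
#' @export
CPI_WARDS <- c("W1", "W2", "W3", "W4", "W5", "W6_transversal")

#' @rdname vocabularies
#' @export
CPI_REASONS <- c("orthopaedic", "geriatric", "neurology", "nutrition",
                 "post_operative")

#' @rdname vocabularies
#' @export
CPI_AGE_BANDS <- c("[18,30)", "[30,40)", "[40,50)", "[50,60)", "[60,70)",
                   "[70+]")

#' @rdname vocabularies
#' @export
CPI_DAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

PACKET_S <- 30L        # length of one detection window, seconds
DAY_S    <- 86400L

#' Convert packet timestamps to calendar dates
#'
#' Timestamps are integer seconds of local clock time since a study
#' epoch (the local midnight starting day 0). The calendar day of a
#' packet is therefore `origin + t %/% 86400`.
#'
#' @param t Integer seconds since the study epoch.
#' @param origin A `Date` (or string) giving the calendar date of day 0.
#' @return A `Date` vector.
#' @export
cpi_date <- function(t, origin) {
  as.Date(origin) + t %/% DAY_S
}

#' Map an age in years to the analysis age band
#'
#' Bands are `[18,30) [30,40) [40,50) [50,60) [60,70) [70+]`.
#'
#' @param age Integer vector of ages in years (may contain `NA`).
#' @return A factor with the band labels.
#' @export
age_band <- function(age) {
  cuts <- c(18, 30, 40, 50, 60, 70, Inf)
  factor(CPI_AGE_BANDS[findInterval(age, cuts)], levels = CPI_AGE_BANDS)
}

#' Day-of-week name and weekend flag
#'
#' @param date A `Date` vector.
#' @return `dow_name()`: factor with levels Monday..Sunday.
#'   `is_weekend()`: logical, `TRUE` for Saturday/Sunday.
#' @export
dow_name <- function(date) {
  # ISO weekday: 1 = Monday ... 7 = Sunday, locale-independent
  idx <- (as.integer(as.Date(date)) + 3L) %% 7L + 1L
  factor(CPI_DAYS[idx], levels = CPI_DAYS)
}

#' @rdname dow_name
#' @export
is_weekend <- function(date) {
  ((as.integer(as.Date(date)) + 3L) %% 7L + 1L) >= 6L
}

#' ISO-8601 week label of a date
#'
#' @param date A `Date` vector.
#' @return Character labels of the form `"2009-W31"`.
#' @export
iso_week <- function(date) {
  format(as.Date(date), "%G-W%V")
}

# t-based 95% confidence interval of a mean; NA bounds when n < 2
t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  se <- sd(x) / sqrt(n)
  q <- qt(1 - (1 - level) / 2, df = n - 1)
  c(mean = m, lo = m - q * se, hi = m + q * se, n = n)
}

# round half up (away from zero for positives), as printed summaries use
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# canonical pair key: lexicographically smaller id first
canonical_pair <- function(a, b) {
  swap <- a > b
  list(id_a = ifelse(swap, b, a), id_b = ifelse(swap, a, b))
}
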
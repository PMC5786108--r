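# Daily contact statistics: contact episodes, person-days (distinct
# daily contacts), pair-days (daily cumulative contact duration), and
# their per-category summaries.
#
# Two quantities drive everything downstream:
#   * number of daily distinct contacts of an individual = how many
#     different people they met that day (contact *frequency*);
#   * daily cumulative duration of a pair = 30 s x number of packets the
#     pair exchanged that day (contact *duration*).

#' Assemble contact episodes from packets
#'
#' Per pair, maximal runs of packets whose inter-packet spacing is at
#' most `gap_tolerance_s` are merged into one episode; the default 60 s
#' lets a single missed packet pass without breaking the episode.
#' Episodes never span midnight: a run crossing a day boundary is split
#' there, both halves keeping at least one packet.
#'
#' @param records Canonical record table ([canonicalize_records()]).
#' @param gap_tolerance_s Maximum spacing (seconds) between consecutive
#'   packets of one episode.
#' @return `data.table(id_a, id_b, start, end, n_packets, duration_s)`
#'   where `start` is the first packet time, `end` the end of the last
#'   30-s window, and `duration_s = 30 * n_packets`.
#' @export
build_episodes <- function(records, gap_tolerance_s = 60) {
  rec <- as.data.table(records)[, .(t, id_a, id_b)]
  if (nrow(rec) == 0L) {
    return(data.table(id_a = character(), id_b = character(),
                      start = numeric(), end = numeric(),
                      n_packets = integer(), duration_s = numeric()))
  }
  setorder(rec, id_a, id_b, t)
  rec[, day := t %/% DAY_S]
  newrun <- c(TRUE, rec$id_a[-1L] != rec$id_a[-nrow(rec)] |
                rec$id_b[-1L] != rec$id_b[-nrow(rec)] |
                rec$t[-1L] - rec$t[-nrow(rec)] > gap_tolerance_s |
                rec$day[-1L] != rec$day[-nrow(rec)])
  rec[, run := cumsum(newrun)]
  ep <- rec[, .(id_a = id_a[1L], id_b = id_b[1L], start = t[1L],
                end = t[.N] + PACKET_S, n_packets = .N), by = run]
  ep[, run := NULL]
  ep[, duration_s := as.numeric(n_packets) * PACKET_S]
  setorder(ep, id_a, id_b, start)
  ep[]
}

#' Daily cumulative contact duration per pair
#'
#' One row per (pair, calendar day) with at least one packet outside the
#' gap schedule: `cum_duration_s = 30 * packet count` plus the number of
#' contact episodes that day.
#'
#' @inheritParams build_episodes
#' @param gaps Gap schedule; packets dated inside a gap are excluded.
#' @param origin Calendar date of day 0.
#' @return `data.table(id_a, id_b, date, n_packets, n_episodes,
#'   cum_duration_s)`.
#' @export
pair_days <- function(records, gaps = NULL, origin = as.Date("2009-07-01"),
                      gap_tolerance_s = 60) {
  rec <- as.data.table(records)[, .(t, id_a, id_b)]
  rec[, date := cpi_date(t, origin)]
  rec <- rec[!in_gap(date, gaps)]
  if (nrow(rec) == 0L) {
    return(data.table(id_a = character(), id_b = character(),
                      date = as.Date(character()), n_packets = integer(),
                      n_episodes = integer(), cum_duration_s = numeric()))
  }
  pd <- rec[, .(n_packets = .N), by = .(id_a, id_b, date)]
  ep <- build_episodes(rec, gap_tolerance_s)
  ep[, date := cpi_date(start, origin)]
  epd <- ep[, .(n_episodes = .N), by = .(id_a, id_b, date)]
  pd <- epd[pd, on = c("id_a", "id_b", "date")]
  pd[, cum_duration_s := as.numeric(n_packets) * PACKET_S]
  setorder(pd, date, id_a, id_b)
  setcolorder(pd, c("id_a", "id_b", "date", "n_packets", "n_episodes",
                    "cum_duration_s"))
  pd[]
}

#' Daily distinct contacts per person
#'
#' One row per (roster individual, presence day) outside the gap
#' schedule. `n_distinct` is the number of different partners met that
#' day and `total_duration_s` the sum of the day's pair durations over
#' those partners. Present days with no packets yield explicit zero
#' rows — they count as zeros in person-level averages.
#'
#' @inheritParams pair_days
#' @param roster Roster table; defines who exists and when.
#' @return `data.table(id, date, n_distinct, total_duration_s)`.
#' @export
person_days <- function(records, roster, gaps = NULL,
                        origin = as.Date("2009-07-01")) {
  ros <- as.data.table(roster)
  # presence grid
  grid <- ros[, .(date = seq(present_from, present_to, by = "day")), by = id]
  grid <- grid[!in_gap(date, gaps)]
  rec <- as.data.table(records)[, .(t, id_a, id_b)]
  rec[, date := cpi_date(t, origin)]
  rec <- rec[!in_gap(date, gaps)]
  long <- rbindlist(list(
    rec[, .(id = id_a, partner = id_b, date)],
    rec[, .(id = id_b, partner = id_a, date)]))
  if (nrow(long)) {
    agg <- long[, .(n_distinct = uniqueN(partner),
                    total_duration_s = .N * as.numeric(PACKET_S)),
                by = .(id, date)]
  } else {
    agg <- data.table(id = character(), date = as.Date(character()),
                      n_distinct = integer(), total_duration_s = numeric())
  }
  out <- agg[grid, on = c("id", "date")]
  out[is.na(n_distinct), `:=`(n_distinct = 0L, total_duration_s = 0)]
  setorder(out, id, date)
  out[]
}

#' Mean daily distinct contacts per category
#'
#' Averages `n_distinct` over the person-days of each category (the
#' default), or first averages within each individual and then across
#' individuals (`grouping = "individual"`). 95% confidence intervals use
#' Student's t on the averaged units; categories with no person-days are
#' omitted with a message.
#'
#' @param pdays Output of [person_days()].
#' @param roster Roster table.
#' @param grouping `"person_day"` (pooled) or `"individual"`.
#' @return `data.table(category, mean, ci_lo, ci_hi, n, unit)`.
#' @export
category_mean_distinct <- function(pdays, roster,
                                   grouping = c("person_day", "individual")) {
  grouping <- match.arg(grouping)
  if (nrow(pdays) == 0L) stop("no person-days to summarize")
  ros <- as.data.table(roster)[, .(id, category)]
  x <- ros[as.data.table(pdays), on = "id"]
  if (grouping == "individual") {
    x <- x[, .(n_distinct = mean(n_distinct)), by = .(category, id)]
  }
  out <- x[!is.na(category),
           {
             ci <- t_ci(n_distinct)
             .(mean = ci[["mean"]], ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               n = as.integer(ci[["n"]]))
           }, by = category]
  missing_cats <- setdiff(unique(ros$category), out$category)
  if (length(missing_cats))
    message("categories with zero person-days omitted: ",
            paste(missing_cats, collapse = ", "))
  out[, unit := if (grouping == "person_day") "person_day" else "individual"]
  setorder(out, -mean)
  out[]
}

#' Mean daily pair duration per unordered category pair
#'
#' Averages the daily cumulative durations of [pair_days()] within each
#' unordered category pair, reported in minutes per day with Student-t
#' 95% confidence intervals. Cells with a single pair-day get an
#' undefined (NA) interval; empty cells are omitted.
#'
#' @param pdays Output of [pair_days()].
#' @param roster Roster table.
#' @return `data.table(cat_1, cat_2, mean_min, ci_lo, ci_hi, n, unit)`
#'   with `cat_1 <= cat_2` alphabetically.
#' @export
category_pair_mean_duration <- function(pdays, roster) {
  if (nrow(pdays) == 0L) stop("no pair-days to summarize")
  ros <- as.data.table(roster)[, .(id, category)]
  x <- copy(as.data.table(pdays))
  x[ros, on = c(id_a = "id"), cat_a := i.category]
  x[ros, on = c(id_b = "id"), cat_b := i.category]
  x <- x[!is.na(cat_a) & !is.na(cat_b)]
  x[, `:=`(cat_1 = pmin(cat_a, cat_b), cat_2 = pmax(cat_a, cat_b))]
  out <- x[, {
    ci <- t_ci(cum_duration_s / 60)
    .(mean_min = ci[["mean"]], ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      n = as.integer(ci[["n"]]))
  }, by = .(cat_1, cat_2)]
  out[, unit := "pair_day"]
  setorder(out, cat_1, cat_2)
  out[]
}

#' Category involvement percentages
#'
#' Given the total number of records and per-category involvement counts
#' (how many records involve at least one member of the category — a
#' record whose members belong to two categories counts once for each),
#' computes the share of all records each category is involved in.
#' Percentages are rounded half-up to two decimals, the convention used
#' when such shares are printed.
#'
#' @param involvement_counts Named numeric vector of per-category
#'   involvement counts, or the output of [involvement_from_records()].
#' @param total_records Total number of records (> 0); each count must
#'   not exceed it.
#' @return `data.table(category, count, percent)`.
#' @export
category_involvement_summary <- function(involvement_counts, total_records) {
  if (length(total_records) != 1L || is.na(total_records) || total_records <= 0)
    stop("total_records must be a single positive count")
  if (any(involvement_counts > total_records))
    stop("involvement count exceeds total records")
  if (is.null(names(involvement_counts)))
    stop("involvement_counts must be named by category")
  data.table(category = names(involvement_counts),
             count = as.numeric(involvement_counts),
             percent = round_half_up(100 * involvement_counts / total_records,
                                     2L))
}
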
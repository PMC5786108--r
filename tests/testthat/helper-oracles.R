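# Independent brute-force oracles and small fixtures shared by the
# tests. The oracles deliberately use plain loops over raw packets so
# they share no code path with the package implementation.

# O(n^2)-style episode assembly: per pair, walk the sorted packet times
# and split whenever the spacing exceeds the tolerance or the calendar
# day changes.
oracle_episodes <- function(records, tol = 60) {
  df <- as.data.frame(records)
  keys <- unique(paste(df$id_a, df$id_b, sep = "\r"))
  out <- list()
  for (key in keys) {
    ids <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ts <- sort(df$t[df$id_a == ids[1] & df$id_b == ids[2]])
    runs <- list()
    cur <- ts[1]
    for (tt in ts[-1]) {
      last <- cur[length(cur)]
      if (tt - last > tol || (tt %/% 86400) != (last %/% 86400)) {
        runs[[length(runs) + 1]] <- cur
        cur <- tt
      } else {
        cur <- c(cur, tt)
      }
    }
    runs[[length(runs) + 1]] <- cur
    for (r in runs) {
      out[[length(out) + 1]] <- data.frame(
        id_a = ids[1], id_b = ids[2], start = r[1], end = r[length(r)] + 30,
        n_packets = length(r), duration_s = 30 * length(r))
    }
  }
  out <- do.call(rbind, out)
  out[order(out$id_a, out$id_b, out$start), , drop = FALSE]
}

# distinct partners of `who` on `date`, counted straight off the packets
oracle_distinct <- function(records, who, date, origin) {
  df <- as.data.frame(records)
  d <- as.Date(origin) + df$t %/% 86400
  hit <- d == date & (df$id_a == who | df$id_b == who)
  partners <- c(df$id_b[hit & df$id_a == who], df$id_a[hit & df$id_b == who])
  length(unique(partners))
}

# cumulative duration of a pair on a date: 30 s per packet
oracle_pair_duration <- function(records, a, b, date, origin) {
  df <- as.data.frame(records)
  d <- as.Date(origin) + df$t %/% 86400
  lo <- pmin(a, b); hi <- pmax(a, b)
  30 * sum(d == date & df$id_a == lo & df$id_b == hi)
}

# random canonical packet stream over a handful of ids and days
random_stream <- function(n, n_ids = 8, n_days = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("X%02d", seq_len(n_ids))
  a <- sample(ids, n, replace = TRUE)
  b <- sample(ids, n, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  t <- 30 * sample.int(n_days * 2880L, length(a), replace = TRUE)
  canonicalize_records(data.frame(t = t, id_a = a, id_b = b))
}

# minimal hand-built roster
tiny_roster <- function(origin = as.Date("2009-07-01"), days = 7) {
  data.frame(
    id = c("P0001", "P0002", "S0001", "S0002"),
    status = c("patient", "patient", "staff", "staff"),
    category = c("patient", "patient", "HCW", "physician"),
    ward = c("W1", "W1", "W1", "W2"),
    age = c(64L, 35L, NA, NA),
    gender = c("F", "M", NA, NA),
    reason = c("geriatric", "neurology", NA, NA),
    present_from = origin,
    present_to = origin + days - 1,
    pvs = FALSE)
}

# small fast synthetic configuration for integration-style tests
small_config <- function(n_days = 5, seed = 1,
                         gap_schedule = cpinet::gap_schedule(), ...) {
  synth_config(
    n_days = n_days,
    ward_census = list(
      W1 = list(patient = 8, HCW = 4, physician = 1),
      W2 = list(patient = 8, HCW = 4, AHS = 2),
      W6_transversal = list(hospital_porter = 2, logistic = 2)),
    gap_schedule = gap_schedule,
    seed = seed, ...)
}
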
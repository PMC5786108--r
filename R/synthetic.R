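# Synthetic long-term-care-facility contact generator.
#
# Emulates a ~310-person, five-ward facility: ward-attached patients
# with long exponential stays, six staff groups (some transversal),
# pair-category-specific episode initiation following an inhomogeneous
# Poisson process with a morning-peaked circadian profile and
# day-of-week modulation, geometric episode lengths on the 30-s grid,
# and battery-change recording gaps.

#' Default category-pair episode rates and episode lengths
#'
#' `default_pair_rates()` returns the symmetric matrix of episode
#' initiation rates (episodes per pair-hour at the circadian reference,
#' i.e. with hour weights normalized to mean 1) between the seven
#' categories. `default_duration_packets()` returns the matching matrix
#' of mean episode lengths in 30-s packets. The defaults are calibrated
#' so that the generated world reproduces the qualitative structure of
#' LTCF sensor studies: porters and physicians meet the most distinct
#' people per day, patients the fewest, while patient-patient contact
#' is by far the longest and porter contact the shortest.
#'
#' @return A 7x7 numeric matrix with category dimnames.
#' @export
default_pair_rates <- function() {
  # Calibrated against the default census and ward factors so that the
  # expected mean daily distinct contacts land near the field-reported
  # ordering porter (~25) > physician (~21) > HCW (~14) > patient (~12):
  # expected distinct partners of category X =
  #   sum over partner groups of n_partners * (1 - exp(-24 * rate * wf)).
  k <- CPI_CATEGORIES
  m <- matrix(0.0010, 7, 7, dimnames = list(k, k))  # staff-staff base
  m["patient", "patient"] <- 0.0006
  m["patient", "HCW"] <- m["HCW", "patient"] <- 0.0028
  m["patient", "reeducation"] <- m["reeducation", "patient"] <- 0.0010
  m["patient", "AHS"] <- m["AHS", "patient"] <- 0.0006
  m["patient", "physician"] <- m["physician", "patient"] <- 0.0065
  m["patient", "hospital_porter"] <- m["hospital_porter", "patient"] <- 0.0068
  m["patient", "logistic"] <- m["logistic", "patient"] <- 0.0004
  st <- setdiff(k, "patient")
  m["physician", st] <- m[st, "physician"] <- 0.0008
  m["hospital_porter", st] <- m[st, "hospital_porter"] <- 0.0012
  m
}

#' @rdname default_pair_rates
#' @export
default_duration_packets <- function() {
  k <- CPI_CATEGORIES
  m <- matrix(6, 7, 7, dimnames = list(k, k))
  m["patient", "patient"] <- 50
  m["patient", "HCW"] <- m["HCW", "patient"] <- 10
  m["patient", "reeducation"] <- m["reeducation", "patient"] <- 40
  m["patient", "physician"] <- m["physician", "patient"] <- 20
  m["patient", "AHS"] <- m["AHS", "patient"] <- 6
  m["patient", "logistic"] <- m["logistic", "patient"] <- 4
  m["hospital_porter", ] <- 3  # porters: many short contacts
  m[, "hospital_porter"] <- 3
  m
}

default_ward_census <- function() {
  list(
    W1 = list(patient = 28, HCW = 16, reeducation = 4, AHS = 5, physician = 2),
    W2 = list(patient = 28, HCW = 16, reeducation = 4, AHS = 5, physician = 2),
    W3 = list(patient = 28, HCW = 16, reeducation = 4, AHS = 5, physician = 2),
    W4 = list(patient = 26, HCW = 16, reeducation = 4, AHS = 5, physician = 2),
    W5 = list(patient = 26, HCW = 16, reeducation = 4, AHS = 5, physician = 2),
    W6_transversal = list(HCW = 8, reeducation = 8, hospital_porter = 7,
                          logistic = 14)
  )
}

# morning-peaked circadian hour weights (rise 5-11 a.m., afternoon
# plateau, small 6-8 p.m. bump, quiet night); normalized internally
default_circadian <- function() {
  c(0.10, 0.08, 0.08, 0.08, 0.10, 0.40, 0.80, 1.50,  # 0-7h
    2.20, 2.60, 2.80, 2.60, 1.80, 1.40, 1.60, 1.60,  # 8-15h
    1.40, 1.20, 1.30, 1.20, 0.80, 0.50, 0.30, 0.15)  # 16-23h
}

#' Build a synthetic-facility configuration
#'
#' All defaults describe one fixed, documented world: a five-ward
#' facility with 136 patients and 174 staff present on any day, mean
#' patient stay of 49 days, morning-peaked contact initiation, fewer but
#' longer contacts at weekends, stronger mixing within a ward than
#' across wards (transversal staff roam freely), and a battery-change
#' gap schedule. See the methods vignette for the calibration rationale.
#'
#' @param n_days Length of the simulated horizon in days.
#' @param origin Calendar date of simulation day 0.
#' @param ward_census Named list `ward -> list(category = count)`.
#' @param pair_rate Symmetric 7x7 category matrix of episode initiation
#'   rates (episodes per pair-hour at the circadian reference).
#' @param duration_mean_packets Symmetric 7x7 category matrix of mean
#'   episode lengths in 30-s packets.
#' @param circadian_weights 24 nonnegative hour weights (normalized to
#'   mean 1 at use).
#' @param dow_multipliers 7 nonnegative multipliers, Monday..Sunday.
#' @param same_ward_boost Initiation multiplier for pairs attached to
#'   the same ward (>= 1).
#' @param cross_ward_mult Initiation multiplier for pairs attached to
#'   two different wards, neither transversal (<= 1); pairs involving
#'   transversal staff use factor 1.
#' @param weekend_duration_mult Multiplier on mean episode length at
#'   weekends (contacts are longer at weekends).
#' @param stay_mean_days Mean patient length of stay (exponential).
#' @param gap_schedule A [gap_schedule()] of invalid recording dates;
#'   default: one two-day battery-change outage mid-horizon when the
#'   horizon is at least 14 days.
#' @param planted_effects Optional named list
#'   `covariate -> c(level = log_rate_multiplier)` used by
#'   [plant_outcome_effects()] for parameter-recovery experiments.
#' @param seed Default integer seed used when none is passed to the
#'   generators.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_days = 30L,
                         origin = as.Date("2009-07-01"),
                         ward_census = default_ward_census(),
                         pair_rate = default_pair_rates(),
                         duration_mean_packets = default_duration_packets(),
                         circadian_weights = default_circadian(),
                         dow_multipliers = c(1, 1, 1, 1.1, 1.1, 0.6, 0.5),
                         same_ward_boost = 6,
                         cross_ward_mult = 0.15,
                         weekend_duration_mult = 1.6,
                         stay_mean_days = 49,
                         gap_schedule = NULL,
                         planted_effects = NULL,
                         seed = 1L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be a positive integer")
  origin <- as.Date(origin)
  if (length(circadian_weights) != 24L || any(circadian_weights < 0))
    stop("circadian_weights must be 24 nonnegative values")
  if (sum(circadian_weights) <= 0) stop("circadian_weights must not be all zero")
  if (length(dow_multipliers) != 7L || any(dow_multipliers < 0))
    stop("dow_multipliers must be 7 nonnegative values")
  stopifnot(same_ward_boost >= 1, cross_ward_mult >= 0, cross_ward_mult <= 1,
            weekend_duration_mult > 0, stay_mean_days > 0)
  if (any(pair_rate < 0)) stop("pair rates must be nonnegative")
  if (any(duration_mean_packets < 1)) stop("duration means must be >= 1 packet")
  if (!isTRUE(all.equal(pair_rate, t(pair_rate))) ||
      !isTRUE(all.equal(duration_mean_packets, t(duration_mean_packets))))
    stop("pair_rate and duration_mean_packets must be symmetric")
  if (length(ward_census) == 0L) stop("ward_census must be nonempty")
  bad_w <- setdiff(names(ward_census), CPI_WARDS)
  if (length(bad_w)) stop("unknown ward(s) in census: ", paste(bad_w, collapse = ", "))
  for (w in names(ward_census)) {
    bad_c <- setdiff(names(ward_census[[w]]), CPI_CATEGORIES)
    if (length(bad_c)) stop("unknown category in census of ", w, ": ",
                            paste(bad_c, collapse = ", "))
    if (any(unlist(ward_census[[w]]) < 0)) stop("census counts must be >= 0")
  }
  if (is.null(gap_schedule)) {
    gap_schedule <- if (n_days >= 14L) {
      mid <- origin + n_days %/% 2
      gap_schedule(mid, mid + 1)
    } else {
      gap_schedule()
    }
  }
  structure(list(
    n_days = n_days, origin = origin, ward_census = ward_census,
    pair_rate = pair_rate, duration_mean_packets = duration_mean_packets,
    circadian_weights = circadian_weights / mean(circadian_weights),
    dow_multipliers = dow_multipliers, same_ward_boost = same_ward_boost,
    cross_ward_mult = cross_ward_mult,
    weekend_duration_mult = weekend_duration_mult,
    stay_mean_days = stay_mean_days, gap_schedule = gap_schedule,
    planted_effects = planted_effects, seed = as.integer(seed)),
    class = "synth_config")
}

# ward -> dominant hospitalization reason (neurologic wards, nutrition
# ward, geriatric ward); remaining mass spread over surgical reasons
ward_reason_probs <- function(ward) {
  p <- setNames(numeric(length(CPI_REASONS)), CPI_REASONS)
  main <- switch(ward, W1 = "neurology", W2 = "neurology", W4 = "neurology",
                 W3 = "nutrition", W5 = "geriatric", "neurology")
  p[main] <- 0.70
  p["orthopaedic"] <- p["orthopaedic"] + 0.15
  p["post_operative"] <- p["post_operative"] + 0.15
  p / sum(p)
}

#' Generate a synthetic roster
#'
#' Staff are present over the whole horizon. Each patient bed holds a
#' succession of patients with independent exponential stays of mean
#' `stay_mean_days`; the first occupant's remaining stay is exponential
#' too (memorylessness makes the census stationary), and intervals are
#' truncated to the horizon, so the daily patient census equals the
#' configured census exactly. Ages are drawn across the bands
#' `[18,30)..[70+]`, genders evenly, and hospitalization reasons from
#' ward-linked distributions (neurologic wards mostly neurology, the
#' nutrition ward mostly nutrition, the geriatric ward mostly
#' geriatric).
#'
#' @param config A [synth_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A roster `data.table` (see [read_roster()]).
#' @export
generate_roster <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  horizon_end <- config$origin + config$n_days - 1L
  rows <- list()
  band_probs <- c(0.08, 0.12, 0.18, 0.25, 0.22, 0.15)
  band_lo <- c(18, 30, 40, 50, 60, 70)
  band_hi <- c(29, 39, 49, 59, 69, 90)
  np <- 0L; ns <- 0L
  for (w in names(config$ward_census)) {
    for (cat in names(config$ward_census[[w]])) {
      cnt <- config$ward_census[[w]][[cat]]
      if (cnt == 0L) next
      if (cat == "patient") {
        for (bed in seq_len(cnt)) {
          d <- 0L  # day index of current occupant's admission
          first <- TRUE
          while (d < config$n_days) {
            stay <- max(1L, ceiling(rexp(1, 1 / config$stay_mean_days)))
            np <- np + 1L
            b <- sample.int(6L, 1L, prob = band_probs)
            rows[[length(rows) + 1L]] <- data.table(
              id = sprintf("P%04d", np), status = "patient",
              category = "patient", ward = w,
              age = as.integer(sample(band_lo[b]:band_hi[b], 1L)),
              gender = sample(c("F", "M"), 1L),
              reason = sample(CPI_REASONS, 1L, prob = ward_reason_probs(w)),
              present_from = config$origin + d,
              present_to = min(config$origin + d + stay - 1L, horizon_end),
              pvs = FALSE)
            d <- d + stay
            first <- FALSE
          }
        }
      } else {
        for (i in seq_len(cnt)) {
          ns <- ns + 1L
          rows[[length(rows) + 1L]] <- data.table(
            id = sprintf("S%04d", ns), status = "staff", category = cat,
            ward = w, age = NA_integer_, gender = NA_character_,
            reason = NA_character_, present_from = config$origin,
            present_to = horizon_end, pvs = FALSE)
        }
      }
    }
  }
  ros <- rbindlist(rows)
  validate_roster(ros)
  setkey(ros, id)
  ros[]
}

#' Per-person contact-rate modifiers from planted covariate effects
#'
#' Multiplies an individual's pair rates by `exp(effect)` for each
#' matching `covariate = level` entry of `config$planted_effects`, so
#' that planted groups have systematically shifted contact levels; the
#' realized modifiers are recorded as ground truth for recovery tests.
#'
#' @param config A [synth_config()] with a `planted_effects` list, e.g.
#'   `list(category = c(hospital_porter = 0.7))`.
#' @param roster Roster the effects apply to.
#' @return `data.table(id, modifier)` with one row per roster member.
#' @export
plant_outcome_effects <- function(config, roster) {
  ros <- as.data.table(roster)
  out <- ros[, .(id, modifier = 1)]
  pe <- config$planted_effects
  if (is.null(pe) || length(pe) == 0L) return(out[])
  for (cov in names(pe)) {
    if (!cov %in% names(ros)) stop("planted covariate not in roster: ", cov)
    eff <- pe[[cov]]
    for (lev in names(eff)) {
      hit <- which(as.character(ros[[cov]]) == lev)
      out[hit, modifier := modifier * exp(eff[[lev]])]
    }
  }
  out[]
}

#' Generate a synthetic CPI packet stream
#'
#' For every co-present eligible pair and every day, episode initiations
#' follow an inhomogeneous Poisson process whose daily intensity is
#' `pair_rate x circadian_weight(hour) x dow_multiplier x ward factor`
#' (`same_ward_boost` within a ward, `cross_ward_mult` across wards,
#' 1 when either member is transversal) times both members' planted
#' modifiers. Each episode emits a run of consecutive 30-s packets with
#' geometric length (mean `duration_mean_packets`, boosted by
#' `weekend_duration_mult` at weekends). Output is canonical,
#' gap-filtered and clipped to the horizon; the same seed reproduces the
#' same stream byte for byte.
#'
#' @inheritParams generate_roster
#' @param roster Roster of individuals (from [generate_roster()] or
#'   [read_roster()]).
#' @return Canonical record `data.table` with a `"truth"` attribute
#'   holding realized per-pair episode counts.
#' @export
generate_contacts <- function(config, roster, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  ros <- as.data.table(roster)
  if (nrow(ros) == 0L) stop("roster is empty")
  set.seed(seed)

  mods <- plant_outcome_effects(config, ros)
  idx <- ros[, .(id, category, ward,
                 day_from = as.integer(present_from - config$origin),
                 day_to = as.integer(present_to - config$origin))]
  idx <- mods[idx, on = "id"]
  n <- nrow(idx)
  if (n < 2L) {
    empty <- canonicalize_records(
      data.table(t = numeric(), id_a = character(), id_b = character()))
    setattr(empty, "truth", data.table())
    return(empty)
  }
  ij <- CJ(i = seq_len(n), j = seq_len(n))[i < j]
  pairs <- data.table(
    id_a = idx$id[ij$i], id_b = idx$id[ij$j],
    cat_a = idx$category[ij$i], cat_b = idx$category[ij$j],
    wf = ifelse(idx$ward[ij$i] == "W6_transversal" |
                  idx$ward[ij$j] == "W6_transversal", 1,
                ifelse(idx$ward[ij$i] == idx$ward[ij$j],
                       config$same_ward_boost, config$cross_ward_mult)),
    mod = idx$modifier[ij$i] * idx$modifier[ij$j],
    from = pmax(idx$day_from[ij$i], idx$day_from[ij$j]),
    to = pmin(idx$day_to[ij$i], idx$day_to[ij$j]))
  pairs[, rate := config$pair_rate[cbind(cat_a, cat_b)]]
  pairs[, dur_mean := config$duration_mean_packets[cbind(cat_a, cat_b)]]
  pairs <- pairs[rate * wf * mod > 0 & from <= to]

  w <- config$circadian_weights            # mean 1
  hour_prob <- w / sum(w)
  horizon_s <- config$n_days * DAY_S
  out <- vector("list", config$n_days)
  ep_counts <- vector("list", config$n_days)
  for (d in seq_len(config$n_days) - 1L) {
    date_d <- config$origin + d
    dowm <- config$dow_multipliers[(as.integer(date_d) + 3L) %% 7L + 1L]
    if (dowm == 0) next
    act <- pairs[from <= d & to >= d]
    if (nrow(act) == 0L) next
    lam <- 24 * act$rate * act$wf * act$mod * dowm
    nep <- rpois(nrow(act), lam)
    hit <- which(nep > 0L)
    if (length(hit)) {
      ep_counts[[d + 1L]] <- data.table(id_a = act$id_a[hit],
                                        id_b = act$id_b[hit],
                                        day = d, n_episodes = nep[hit])
    }
    if (!length(hit)) next
    reps <- nep[hit]
    eid_a <- rep(act$id_a[hit], reps)
    eid_b <- rep(act$id_b[hit], reps)
    m <- rep(act$dur_mean[hit], reps)
    if (is_weekend(date_d)) m <- m * config$weekend_duration_mult
    nevents <- length(eid_a)
    hr <- sample.int(24L, nevents, replace = TRUE, prob = hour_prob) - 1L
    slot <- sample.int(120L, nevents, replace = TRUE) - 1L
    start <- d * DAY_S + hr * 3600L + slot * PACKET_S
    npk <- 1L + rgeom(nevents, prob = 1 / m)
    tlist <- sequence(npk, from = start, by = PACKET_S)
    out[[d + 1L]] <- data.table(
      t = tlist,
      id_a = rep(eid_a, npk),
      id_b = rep(eid_b, npk))
  }
  rec <- rbindlist(out)
  if (nrow(rec) == 0L) {
    rec <- data.table(t = numeric(), id_a = character(), id_b = character())
  } else {
    rec <- rec[t < horizon_s]
    rec <- rec[!in_gap(cpi_date(t, config$origin), config$gap_schedule)]
  }
  rec <- canonicalize_records(rec)
  truth <- rbindlist(ep_counts)
  setattr(rec, "truth", truth)
  rec
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: roster plus contact stream plus ground truth.
#' The roster and contact substreams use seeds derived from `seed` so
#' the two stages are individually reproducible.
#'
#' @inheritParams generate_roster
#' @return A list with components `roster`, `records`, `config` and
#'   `truth` (realized per-pair daily episode counts).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  ros <- generate_roster(config, seed = substream_seed(seed, 1L))
  rec <- generate_contacts(config, ros, seed = substream_seed(seed, 2L))
  list(roster = ros, records = rec, config = config,
       truth = attr(rec, "truth"))
}

# derive independent per-stage seeds, kept within 32-bit integer range
substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}
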
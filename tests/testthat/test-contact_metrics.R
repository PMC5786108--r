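# Episodes, person-days, pair-days and category summaries, checked
# against brute-force oracles and hand computations.

origin <- as.Date("2009-07-01")

test_that("episode assembly handles runs, gaps and midnight", {
  rec <- canonicalize_records(data.frame(
    t = c(0, 30, 60), id_a = "A", id_b = "B"))
  ep <- build_episodes(rec)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_s, 90)
  expect_equal(ep$n_packets, 3L)

  rec2 <- canonicalize_records(data.frame(
    t = c(0, 120), id_a = "A", id_b = "B"))
  ep2 <- build_episodes(rec2, gap_tolerance_s = 60)
  expect_equal(nrow(ep2), 2L)
  expect_equal(ep2$duration_s, c(30, 30))

  # tolerance 60 lets one missed packet through
  rec3 <- canonicalize_records(data.frame(
    t = c(0, 60), id_a = "A", id_b = "B"))
  expect_equal(nrow(build_episodes(rec3, 60)), 1L)

  # packets straddling midnight split, both halves nonempty
  rec4 <- canonicalize_records(data.frame(
    t = c(86370, 86400), id_a = "A", id_b = "B"))
  ep4 <- build_episodes(rec4, 60)
  expect_equal(nrow(ep4), 2L)
  expect_equal(ep4$n_packets, c(1L, 1L))
})

test_that("episodes match the brute-force oracle on a random stream", {
  rec <- random_stream(10000, n_ids = 10, n_days = 4, seed = 42)
  ep <- build_episodes(rec, 60)
  orc <- oracle_episodes(rec, 60)
  expect_equal(as.data.frame(ep), as.data.frame(orc), ignore_attr = TRUE)
})

test_that("episode assembly is invariant to input record order", {
  rec <- random_stream(2000, seed = 3)
  shuffled <- as.data.frame(rec)[sample(nrow(rec)), ]
  expect_equal(as.data.frame(build_episodes(shuffled)),
               as.data.frame(build_episodes(rec)))
})

test_that("pair-days aggregate packets per pair and date", {
  rec <- canonicalize_records(data.frame(
    t = c(30, 60, 90, 120, 86430),
    id_a = "A", id_b = "B"))
  pd <- pair_days(rec, NULL, origin)
  expect_equal(nrow(pd), 2L)
  expect_equal(pd$cum_duration_s, c(120, 30))
  expect_equal(pd$date, origin + 0:1)
  expect_true(all(pd$cum_duration_s %% 30 == 0))
})

test_that("pair-day durations conserve total packet count", {
  rec <- random_stream(5000, n_ids = 12, n_days = 5, seed = 8)
  pd <- pair_days(rec, NULL, origin)
  expect_identical(sum(pd$cum_duration_s), 30 * as.numeric(nrow(rec)))
  # spot-check one pair-day against the oracle
  row <- as.data.frame(pd)[17, ]
  expect_equal(row$cum_duration_s,
               oracle_pair_duration(rec, row$id_a, row$id_b, row$date, origin))
})

test_that("person-days count distinct partners, with explicit zeros", {
  ros <- tiny_roster(origin, days = 2)
  rec <- canonicalize_records(data.frame(
    t = c(30, 60, 90, 120),
    id_a = c("P0001", "P0001", "P0001", "P0001"),
    id_b = c("P0002", "P0002", "P0002", "S0001")))
  pd <- person_days(rec, ros, NULL, origin)
  a <- pd[pd$id == "P0001" & pd$date == origin, ]
  expect_equal(a$n_distinct, 2L)
  expect_equal(a$total_duration_s, 120)
  # present day with no records is an explicit zero
  z <- pd[pd$id == "S0002" & pd$date == origin, ]
  expect_equal(z$n_distinct, 0L)
  expect_equal(z$total_duration_s, 0)
  # one row per (individual, presence day)
  expect_equal(nrow(pd), 4L * 2L)
})

test_that("person-day distinct counts match the oracle on a synthetic stream", {
  cfg <- small_config(n_days = 4)
  ds <- generate_dataset(cfg, seed = 12)
  pd <- person_days(ds$records, ds$roster, NULL, cfg$origin)
  nonzero <- as.data.frame(pd[pd$n_distinct > 0, ])
  pick <- nonzero[seq(1, nrow(nonzero), length.out = 25), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$n_distinct[i],
                 oracle_distinct(ds$records, pick$id[i], pick$date[i],
                                 cfg$origin))
  }
})

test_that("n_distinct equals the number of the day's pair-days per person", {
  cfg <- small_config(n_days = 3)
  ds <- generate_dataset(cfg, seed = 13)
  pd <- person_days(ds$records, ds$roster, NULL, cfg$origin)
  ppd <- pair_days(ds$records, NULL, cfg$origin)
  long <- rbind(
    data.frame(id = ppd$id_a, date = ppd$date),
    data.frame(id = ppd$id_b, date = ppd$date))
  tab <- aggregate(rep(1L, nrow(long)), by = long, FUN = sum)
  m <- merge(as.data.frame(pd), tab, by = c("id", "date"), all.x = TRUE)
  m$x[is.na(m$x)] <- 0L
  expect_equal(m$n_distinct, m$x)
})

test_that("gap days are excluded from person-days and pair-days", {
  ros <- tiny_roster(origin, days = 3)
  g <- gap_schedule(origin + 1, origin + 1)
  rec <- canonicalize_records(data.frame(
    t = c(30, 86430, 172830), id_a = "P0001", id_b = "P0002"))
  pd <- person_days(rec, ros, g, origin)
  expect_false(any(pd$date == origin + 1))
  expect_equal(nrow(pd), 4L * 2L)  # 3 days minus 1 gap day, 4 people
  ppd <- pair_days(rec, g, origin)
  expect_equal(nrow(ppd), 2L)
})

test_that("category means and t-CIs follow hand computations", {
  ros <- tiny_roster(origin, days = 2)
  pd <- data.frame(id = c("P0001", "P0001", "S0001", "S0001"),
                   date = rep(origin + 0:1, 2),
                   n_distinct = c(2L, 4L, 3L, 3L),
                   total_duration_s = c(60, 120, 90, 90))
  cm <- category_mean_distinct(pd, ros)
  pat <- cm[cm$category == "patient", ]
  expect_equal(pat$mean, 3.0)
  # hand t-interval: mean 3, sd sqrt(2), n 2 -> 3 +/- 12.7062*1
  expect_equal(pat$ci_lo, 3 - qt(0.975, 1) * 1, tolerance = 1e-9)
  hcw <- cm[cm$category == "HCW", ]
  expect_equal(hcw$mean, 3.0)
  expect_equal(hcw$ci_lo, 3.0)  # degenerate: zero variance
  expect_equal(hcw$ci_hi, 3.0)
})

test_that("per-individual averaging option changes the unit", {
  ros <- tiny_roster(origin, days = 2)
  pd <- data.frame(id = c("P0001", "P0001", "P0002"),
                   date = c(origin, origin + 1, origin),
                   n_distinct = c(0L, 4L, 4L),
                   total_duration_s = c(0, 120, 120))
  pooled <- category_mean_distinct(pd, ros, "person_day")
  byind <- category_mean_distinct(pd, ros, "individual")
  expect_equal(pooled[pooled$category == "patient", ]$mean, 8 / 3)
  expect_equal(byind[byind$category == "patient", ]$mean, 3)  # (2 + 4)/2
  expect_equal(byind[byind$category == "patient", ]$n, 2L)
})

test_that("pair duration summaries are symmetric in category order", {
  ros <- tiny_roster(origin, days = 1)
  pdays <- data.frame(id_a = c("P0001", "S0001"), id_b = c("S0001", "P0002"),
                      date = origin, n_packets = c(2L, 4L),
                      n_episodes = 1L, cum_duration_s = c(60, 120))
  out <- category_pair_mean_duration(pdays, ros)
  cell <- out[out$cat_1 == "HCW" & out$cat_2 == "patient", ]
  expect_equal(cell$mean_min, 1.5)   # (1 + 2)/2 minutes
  expect_equal(cell$n, 2L)
  # no reversed duplicate row exists
  expect_equal(nrow(out), 1L)
})

test_that("involvement percentages reproduce printed-count arithmetic", {
  counts <- c(patient = 2279515, HCW = 944142, reeducation = 94100,
              AHS = 109789, hospital_porter = 36791, physician = 33406)
  out <- category_involvement_summary(counts, 2671832)
  expect_equal(out$percent[out$category == "patient"], 85.32)
  expect_equal(out$percent[out$category == "physician"], 1.25)
  expect_equal(out$percent[out$category == "HCW"], 35.34)
  expect_equal(category_involvement_summary(c(x = 50), 50)$percent, 100)
  expect_error(category_involvement_summary(c(x = 1), 0), "positive")
  expect_error(category_involvement_summary(c(x = 2), 1), "exceeds")
})
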
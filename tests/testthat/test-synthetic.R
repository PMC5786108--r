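# Synthetic facility generator: determinism, census, stays, Poisson
# episode counts, circadian/weekend structure, planted effects.

test_that("generation is deterministic given config + seed", {
  cfg <- small_config(n_days = 3)
  d1 <- generate_dataset(cfg, seed = 9)
  d2 <- generate_dataset(cfg, seed = 9)
  expect_identical(as.data.frame(d1$roster), as.data.frame(d2$roster))
  expect_identical(as.data.frame(d1$records), as.data.frame(d2$records))
  d3 <- generate_dataset(cfg, seed = 10)
  expect_false(identical(as.data.frame(d1$records), as.data.frame(d3$records)))
})

test_that("roster respects census and intervals", {
  cfg <- synth_config(n_days = 7,
                      ward_census = list(W1 = list(patient = 2, HCW = 1)),
                      gap_schedule = gap_schedule())
  ros <- generate_roster(cfg, seed = 1)
  expect_equal(nrow(ros) >= 3, TRUE)  # beds may host successive patients
  expect_true(all(ros$present_from <= ros$present_to))
  staff <- ros[ros$status == "staff", ]
  expect_equal(staff$present_from, cfg$origin)
  expect_equal(staff$present_to, cfg$origin + 6)
  expect_error(synth_config(n_days = 0), "positive")
})

test_that("default config keeps the daily patient census near 136", {
  cfg <- synth_config(n_days = 21, gap_schedule = gap_schedule())
  for (s in c(2, 5)) {
    ros <- generate_roster(cfg, seed = s)
    mid <- cfg$origin + 10
    n_pat <- sum(ros$status == "patient" & ros$present_from <= mid &
                   ros$present_to >= mid)
    expect_gt(n_pat, 136 * 0.8)
    expect_lt(n_pat, 136 * 1.2)
  }
})

test_that("realized untruncated stays average the configured mean", {
  cfg <- synth_config(n_days = 3000, stay_mean_days = 49,
                      ward_census = list(W1 = list(patient = 200)),
                      gap_schedule = gap_schedule())
  ros <- generate_roster(cfg, seed = 4)
  # drop horizon-truncated last occupants of each bed
  full <- ros[ros$present_to < cfg$origin + cfg$n_days - 1, ]
  stays <- as.numeric(full$present_to - full$present_from) + 1
  expect_gt(length(stays), 5000)
  expect_lt(abs(mean(stays) - 49), 1)
})

test_that("zero rates and zeroed weekends produce no records", {
  cfg0 <- small_config(n_days = 3,
                       pair_rate = matrix(0, 7, 7,
                         dimnames = list(CPI_CATEGORIES, CPI_CATEGORIES)))
  ds <- generate_dataset(cfg0, seed = 1)
  expect_equal(nrow(ds$records), 0L)

  # 2009-07-01 is a Wednesday; days 4/5 of the horizon are Sat/Sun
  cfgw <- small_config(n_days = 7,
                       dow_multipliers = c(1, 1, 1, 1, 1, 0, 0))
  ds <- generate_dataset(cfgw, seed = 2)
  dows <- weekdays(cpi_date(ds$records$t, cfgw$origin))
  expect_false(any(dows %in% c("Saturday", "Sunday")))
})

test_that("episode counts follow the Poisson oracle for one flat pair", {
  # one isolated pair, constant circadian profile, no weekend effect
  rate <- 0.01
  pr <- matrix(0, 7, 7, dimnames = list(CPI_CATEGORIES, CPI_CATEGORIES))
  pr["HCW", "hospital_porter"] <- pr["hospital_porter", "HCW"] <- rate
  cfg <- synth_config(
    n_days = 1000,
    ward_census = list(W6_transversal = list(HCW = 1, hospital_porter = 1)),
    pair_rate = pr, circadian_weights = rep(1, 24),
    dow_multipliers = rep(1, 7), gap_schedule = gap_schedule())
  ros <- generate_roster(cfg, seed = 5)
  rec <- generate_contacts(cfg, ros, seed = 5)
  realized <- sum(attr(rec, "truth")$n_episodes)
  expected <- 24 * rate * 1000   # transversal pair: ward factor 1
  expect_lt(abs(realized - expected), 3 * sqrt(expected))
})

test_that("no generated record falls inside a gap interval", {
  g <- gap_schedule("2009-07-03", "2009-07-04")
  cfg <- small_config(n_days = 7, gap_schedule = g)
  ds <- generate_dataset(cfg, seed = 6)
  expect_gt(nrow(ds$records), 0)
  dates <- cpi_date(ds$records$t, cfg$origin)
  expect_false(any(dates >= as.Date("2009-07-03") &
                     dates <= as.Date("2009-07-04")))
})

test_that("circadian weights shape the hourly packet distribution", {
  cfg <- small_config(n_days = 10)
  ds <- generate_dataset(cfg, seed = 7)
  hr <- (ds$records$t %% 86400) %/% 3600
  morning <- sum(hr %in% 8:11)
  night <- sum(hr %in% 0:3)
  expect_gt(morning, 5 * night)
})

test_that("planted effects validate covariates and shift contact levels", {
  cfg <- small_config(n_days = 2)
  ros <- generate_roster(cfg, seed = 1)
  expect_equal(plant_outcome_effects(cfg, ros)$modifier,
               rep(1, nrow(ros)))
  cfg_bad <- small_config(n_days = 2,
                          planted_effects = list(shoe_size = c("44" = 1)))
  expect_error(plant_outcome_effects(cfg_bad, ros), "shoe_size")

  # porters vs HCW with identical base rates: only the planted effect
  # separates them, in expectation over 50 seeds
  pr <- matrix(0, 7, 7, dimnames = list(CPI_CATEGORIES, CPI_CATEGORIES))
  pr["patient", ] <- pr[, "patient"] <- 0.004
  pr["patient", "patient"] <- 0
  base <- list(
    W1 = list(patient = 12),
    W6_transversal = list(hospital_porter = 3, HCW = 3))
  diffs <- vapply(1:50, function(s) {
    cfg <- synth_config(n_days = 2, ward_census = base, pair_rate = pr,
                        gap_schedule = gap_schedule(),
                        planted_effects = list(
                          category = c(hospital_porter = 0.7)))
    ds <- generate_dataset(cfg, seed = s)
    pd <- person_days(ds$records, ds$roster, NULL, cfg$origin)
    cm <- category_mean_distinct(pd, ds$roster)
    m <- setNames(cm$mean, cm$category)
    m[["hospital_porter"]] - m[["HCW"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("config validation rejects bad inputs", {
  expect_error(synth_config(circadian_weights = rep(1, 23)), "24")
  expect_error(synth_config(dow_multipliers = rep(-1, 7)), "nonnegative")
  expect_error(synth_config(ward_census = list(W9 = list(patient = 1))), "W9")
  expect_error(synth_config(stay_mean_days = 0))
  bad <- default_pair_rates(); bad[1, 2] <- bad[1, 2] + 1
  expect_error(synth_config(pair_rate = bad), "symmetric")
})
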
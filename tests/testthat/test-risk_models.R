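# Outcome construction, dichotomization and the ward-random-intercept
# logistic model.

origin <- as.Date("2009-07-01")

make_pd <- function(ids, days, origin, freq = NULL, dur = NULL) {
  g <- expand.grid(id = ids, date = origin + seq_len(days) - 1,
                   stringsAsFactors = FALSE)
  g$n_distinct <- if (is.null(freq)) 1L else freq
  g$total_duration_s <- if (is.null(dur)) 30 else dur
  g
}

test_that("outcome tables join covariates and apply exclusions", {
  ros <- tiny_roster(origin, days = 3)
  pd <- make_pd(ros$id, 3, origin)
  staff <- build_outcome_table(pd, ros, "staff")
  expect_equal(nrow(staff), 2L * 3L)
  expect_true(all(c("category", "day_of_week", "ward") %in% names(staff)))
  pats <- build_outcome_table(pd, ros, "patients")
  expect_equal(nrow(pats), 2L * 3L)
  expect_equal(levels(pats$age_band), CPI_AGE_BANDS)

  # PVS patients and administration staff contribute no rows
  ros2 <- ros
  ros2$pvs[ros2$id == "P0001"] <- TRUE
  ros2$category[ros2$id == "S0001"] <- "administration"
  ros2$status[ros2$id == "S0001"] <- "staff"
  expect_equal(nrow(build_outcome_table(pd, ros2, "patients")), 3L)
  expect_equal(nrow(build_outcome_table(pd, ros2, "staff")), 3L)
})

test_that("row count equals presence-days outside gaps", {
  cfg <- small_config(n_days = 6)
  ds <- generate_dataset(cfg, seed = 41)
  g <- gap_schedule(cfg$origin + 2, cfg$origin + 2)
  pd <- person_days(ds$records, ds$roster, g, cfg$origin)
  tab <- build_outcome_table(pd, ds$roster, "staff")
  ros <- as.data.frame(ds$roster)
  staff <- ros[ros$status == "staff", ]
  expected <- sum(vapply(seq_len(nrow(staff)), function(i) {
    d <- seq(staff$present_from[i], staff$present_to[i], by = "day")
    sum(!(d >= cfg$origin + 2 & d <= cfg$origin + 2))
  }, numeric(1)))
  expect_equal(nrow(tab), expected)
})

test_that("dichotomization thresholds follow mean + k*sd with ties low", {
  ros <- tiny_roster(origin, days = 5)
  pd <- make_pd("S0001", 5, origin, freq = 1:5, dur = 30 * (1:5))
  tab <- build_outcome_table(pd, ros, "staff")
  d0 <- dichotomize(tab, 0)
  th0 <- attr(d0, "thresholds")
  expect_equal(th0$threshold[th0$outcome == "freq_value"], 3)
  expect_equal(d0$high_freq, as.integer(tab$freq_value > 3))
  expect_equal(sum(d0$high_freq), 2L)  # {4, 5}; the tie rule is strict >
  d1 <- dichotomize(tab, 1)
  th1 <- attr(d1, "thresholds")
  expect_equal(th1$threshold[th1$outcome == "freq_value"],
               3 + sd(1:5), tolerance = 1e-12)  # 4.5811 with sample sd
  expect_equal(sum(d1$high_freq), 1L)  # only {5}
  expect_error(dichotomize(tab, 5), "k must be")
  # zero variance warns and uses the mean
  pdc <- make_pd("S0001", 5, origin, freq = 3L, dur = 90)
  tabc <- build_outcome_table(pdc, ros, "staff")
  suppressWarnings(expect_warning(dc <- dichotomize(tabc, 1),
                                  "zero variance"))
  expect_equal(sum(dc$high_freq), 0L)
})

test_that("mean + 3sd on near-normal values isolates the extreme tail", {
  set.seed(99)
  n <- 20000
  ros <- data.frame(id = sprintf("S%04d", 1:n), status = "staff",
                    category = "HCW", ward = "W1", age = NA, gender = NA,
                    reason = NA, present_from = origin, present_to = origin,
                    pvs = FALSE)
  pd <- make_pd(ros$id, 1, origin, freq = round(rnorm(n, 50, 10)),
                dur = 30 * rpois(n, 20))
  tab <- build_outcome_table(pd, ros, "staff")
  d3 <- dichotomize(tab, 3)
  p <- mean(d3$high_freq)
  expect_gt(p, 0.0002)  # normal tail beyond 3 sd ~ 0.13%
  expect_lt(p, 0.004)
})

test_that("the proportion high is non-increasing in k", {
  cfg <- small_config(n_days = 6)
  ds <- generate_dataset(cfg, seed = 43)
  pd <- person_days(ds$records, ds$roster, NULL, cfg$origin)
  for (pop in c("staff", "patients")) {
    tab <- build_outcome_table(pd, ds$roster, pop)
    for (oc in c("high_freq", "high_dur")) {
      props <- vapply(0:3, function(k) mean(dichotomize(tab, k)[[oc]]),
                      numeric(1))
      expect_true(all(diff(props) <= 0))
    }
  }
})

test_that("glmm estimates agree with plain logistic when ward variance is 0", {
  sim <- simulate_glmm_table(
    n = 4000,
    factors = list(category = c(HCW = 0.6, physician = 0.2, AHS = 0.2)),
    beta = list(category = c(physician = 1.0, AHS = -0.5)),
    intercept = -1, ward_sd = 0, seed = 5)
  sim$high_freq <- sim$y
  data.table::setattr(sim, "population", NULL)
  fit <- fit_glmm(sim, "high_freq", factors = list(category = "HCW"),
                  lrt = FALSE)
  expect_lte(fit$ranef_var, 0.05)
  ref <- glm(y ~ category, family = binomial, data = sim)
  co <- fit$coefficients[!is.na(fit$coefficients$factor), ]
  for (i in seq_len(nrow(co))) {
    g <- coef(summary(ref))[co$term[i], ]
    expect_lt(abs(co$estimate[i] - g["Estimate"]), 2 * g["Std. Error"])
  }
})

test_that("wald stars, separation and degenerate outcomes are flagged", {
  expect_equal(cpinet:::stars_for(c(0.2, 0.04, 0.009, 5e-4, NA)),
               c("", "*", "**", "***", ""))
  # complete separation: one level always high
  set.seed(1)
  n <- 400
  dat <- data.frame(
    ward = sample(paste0("W", 1:3), n, TRUE),
    category = factor(rep(c("HCW", "physician"), each = n / 2)),
    high_freq = c(rbinom(n / 2, 1, 0.3), rep(1L, n / 2)))
  fit <- fit_glmm(dat, "high_freq", factors = list(category = "HCW"),
                  lrt = FALSE)
  expect_true(length(fit$separation) >= 1)
  # degenerate outcome: no crash, flagged
  dat$high_freq <- 0L
  fit0 <- fit_glmm(dat, "high_freq", factors = list(category = "HCW"))
  expect_false(fit0$converged)
  expect_match(fit0$note, "degenerate")
})

test_that("a strongly planted effect is detected by Wald and LRT", {
  sim <- simulate_glmm_table(
    n = 5000,
    factors = list(category = c(HCW = 0.7, hospital_porter = 0.3)),
    beta = list(category = c(hospital_porter = log(10))),
    intercept = -2, ward_sd = 0.3, seed = 17)
  sim$high_freq <- sim$y
  fit <- fit_glmm(sim, "high_freq", factors = list(category = "HCW"))
  co <- fit$coefficients[fit$coefficients$level %in% "hospital_porter", ]
  expect_gt(co$or, 5)
  expect_lt(co$ci_lo, 10); expect_gt(co$ci_hi, 10)
  expect_lt(fit$lrt$p_lrt, 1e-6)
  expect_equal(lrt_factor(fit, "category"), fit$lrt$p_lrt)
})

test_that("sensitivity analysis keeps the planted OR sign across k", {
  cfg <- small_config(n_days = 6,
                      planted_effects = list(category = c(hospital_porter = 1)))
  ds <- generate_dataset(cfg, seed = 44)
  pd <- person_days(ds$records, ds$roster, NULL, cfg$origin)
  tab <- build_outcome_table(pd, ds$roster, "staff")
  sens <- sensitivity_analysis(tab, "high_freq", k_list = 0:1)
  por <- sens[sens$level %in% "hospital_porter" & !is.na(sens$or), ]
  expect_gt(nrow(por), 0)
  expect_true(all(por$or > 1))
  one <- sensitivity_analysis(tab, "high_freq", k_list = 1)
  expect_equal(unique(one$k), 1)
})
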
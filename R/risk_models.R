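# Risk-factor analysis of dichotomized daily contact outcomes.
#
# Person-days are the unit of analysis. Daily distinct contacts and
# daily cumulative duration are dichotomized at mean + k*sd of the
# population's person-day distribution (k = 1 for the main analysis,
# k in {0,2,3} as sensitivity analyses) and modelled with a logistic
# mixed model carrying a single ward-level random intercept:
#
#   logit P(high_ij = 1) = x_ij' beta + u_w(i),   u_w ~ N(0, sigma_w^2)
#
# Factor-level inference is Wald (estimate, OR, 95% CI, significance
# stars); whole-factor inference is a likelihood-ratio test against the
# model without the factor.

STAFF_EXCLUDED_CATEGORIES <- c("administration", "animation")

#' Build the person-day outcome table for one population
#'
#' Joins person-day contact values with roster covariates for either the
#' staff or the patient population. Administration and animation staff
#' and patients in a persistent vegetative state are excluded, as are
#' rows with missing covariates (counted in the `"dropped"` attribute).
#'
#' @param pdays Output of [person_days()].
#' @param roster Roster table.
#' @param population `"staff"` or `"patients"`.
#' @return A `data.table` with `id`, `date`, `ward`, `day_of_week`,
#'   population covariates (`category` for staff; `reason`, `age_band`,
#'   `gender` for patients), `freq_value` and `dur_value`.
#' @export
build_outcome_table <- function(pdays, roster,
                                population = c("staff", "patients")) {
  population <- match.arg(population)
  ros <- as.data.table(roster)
  keep <- if (population == "staff") {
    ros[status == "staff" & !category %in% STAFF_EXCLUDED_CATEGORIES]
  } else {
    ros[status == "patient" & pvs == FALSE]
  }
  x <- as.data.table(pdays)[id %chin% keep$id]
  x <- keep[x, on = "id"]
  x[, day_of_week := dow_name(date)]
  x[, freq_value := as.numeric(n_distinct)]
  x[, dur_value := as.numeric(total_duration_s)]
  n0 <- nrow(x)
  if (population == "patients") {
    x <- x[!is.na(reason) & !is.na(age) & !is.na(gender)]
    x[, age_band := age_band(age)]
    out <- x[, .(id, date, ward, day_of_week, reason = factor(reason),
                 age_band, gender = factor(gender, levels = c("F", "M")),
                 freq_value, dur_value)]
  } else {
    out <- x[, .(id, date, ward, day_of_week,
                 category = factor(category),
                 freq_value, dur_value)]
  }
  setattr(out, "dropped", n0 - nrow(out))
  setattr(out, "population", population)
  out[]
}

#' Dichotomize contact outcomes at mean + k*sd
#'
#' Adds binary columns `high_freq` and `high_dur`: value strictly above
#' `mean + k * sd` of the table's person-day distribution (sample sd;
#' ties classify as low). Thresholds are computed per outcome on the
#' supplied table — i.e. per population when the table came from
#' [build_outcome_table()].
#'
#' @param table Outcome table ([build_outcome_table()]).
#' @param k Threshold multiplier, one of 0, 1, 2, 3.
#' @return The table with `high_freq`/`high_dur` columns and a
#'   `"thresholds"` attribute (`data.table(outcome, k, mean, sd,
#'   threshold)`).
#' @export
dichotomize <- function(table, k = 1L) {
  if (!k %in% 0:3) stop("k must be one of 0, 1, 2, 3")
  x <- copy(as.data.table(table))
  th <- rbindlist(lapply(c(freq = "freq_value", dur = "dur_value"),
                         function(col) {
    m <- mean(x[[col]]); s <- sd(x[[col]])
    if (is.na(s) || s == 0) {
      warning("zero variance in ", col, "; threshold equals the mean")
      s <- 0
    }
    data.table(outcome = col, k = k, mean = m, sd = s,
               threshold = m + k * s)
  }))
  x[, high_freq := as.integer(freq_value > th[outcome == "freq_value", threshold])]
  x[, high_dur := as.integer(dur_value > th[outcome == "dur_value", threshold])]
  setattr(x, "thresholds", th)
  setattr(x, "population", attr(table, "population", exact = TRUE))
  x[]
}

default_model_factors <- function(population) {
  if (population == "staff") {
    list(category = "HCW", day_of_week = "Wednesday")
  } else {
    list(reason = "orthopaedic", age_band = "[50,60)", gender = "F",
         day_of_week = "Wednesday")
  }
}

#' Fit the ward-random-intercept logistic model
#'
#' Fits `outcome ~ factors + (1 | ward)` by Laplace-approximated maximum
#' likelihood ([lme4::glmer()]). Reference levels are set per factor
#' (defaults: staff — category ref HCW, day ref Wednesday; patients —
#' reason ref orthopaedic, age ref `[50,60)`, gender ref F, day ref
#' Wednesday). Each level gets a Wald 95% CI on the log-odds scale and
#' significance stars (* <0.05, ** <0.01, *** <0.001); each factor gets
#' a likelihood-ratio p-value against the model dropping it. Complete
#' separation is flagged when |log-OR| exceeds 15.
#'
#' @param table Dichotomized outcome table ([dichotomize()]).
#' @param outcome `"high_freq"` or `"high_dur"`.
#' @param factors Named list `factor -> reference level`; default per
#'   the table's population.
#' @param lrt Compute per-factor likelihood-ratio tests (refits one
#'   reduced model per factor).
#' @return A `cpi_glmm` object: list with `coefficients` (per-level
#'   table), `lrt` (per-factor table), `ranef_var`, `n_obs`,
#'   `converged`, `separation`, `logLik` and the underlying `model`.
#' @export
fit_glmm <- function(table, outcome = c("high_freq", "high_dur"),
                     factors = NULL, lrt = TRUE) {
  outcome <- match.arg(outcome)
  x <- as.data.table(table)
  if (!outcome %in% names(x)) stop("outcome column missing; run dichotomize()")
  population <- attr(table, "population", exact = TRUE)
  if (is.null(factors)) {
    if (is.null(population)) stop("factors must be given when the table ",
                                  "carries no population attribute")
    factors <- default_model_factors(population)
  }
  if (uniqueN(x$ward) < 2L) stop("need at least 2 wards for a random intercept")
  dat <- as.data.frame(x)
  for (f in names(factors)) {
    if (!f %in% names(dat)) stop("factor not in table: ", f)
    dat[[f]] <- droplevels(factor(dat[[f]]))
    if (!factors[[f]] %in% levels(dat[[f]]))
      stop("reference level '", factors[[f]], "' absent for factor ", f)
    dat[[f]] <- stats::relevel(dat[[f]], ref = factors[[f]])
  }
  dat$ward <- factor(dat$ward)
  if (all(dat[[outcome]] == dat[[outcome]][1L])) {
    return(structure(list(outcome = outcome, coefficients = data.table(),
                          lrt = data.table(), ranef_var = NA_real_,
                          n_obs = nrow(dat), converged = FALSE,
                          separation = character(), logLik = NA_real_,
                          model = NULL,
                          note = "degenerate outcome: all values identical"),
                     class = "cpi_glmm"))
  }
  fml <- as.formula(paste(outcome, "~",
                          paste(names(factors), collapse = " + "),
                          "+ (1 | ward)"))
  fit <- suppressWarnings(
    lme4::glmer(fml, data = dat, family = binomial,
                control = lme4::glmerControl(check.conv.singular = "ignore")))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  est <- lme4::fixef(fit)
  # near-separated fits can trigger a fallback vcov computation
  se <- sqrt(diag(as.matrix(suppressWarnings(vcov(fit)))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  co <- data.table(term = names(est), estimate = est, se = se,
                   or = exp(est), ci_lo = exp(est - 1.96 * se),
                   ci_hi = exp(est + 1.96 * se), p_wald = p)
  co[, stars := stars_for(p_wald)]
  # map terms back to (factor, level)
  co[, factor := NA_character_][, level := NA_character_]
  for (f in names(factors)) {
    hit <- startsWith(co$term, f) & co$term != "(Intercept)"
    co[hit, `:=`(factor = f, level = sub(paste0("^", f), "", term))]
  }
  sep <- co[!is.na(factor) & abs(estimate) > 15, term]
  lrt_dt <- data.table(factor = character(), df = integer(),
                       chisq = numeric(), p_lrt = numeric())
  if (lrt) {
    for (f in names(factors)) {
      red_fml <- as.formula(paste(outcome, "~",
                                  paste(setdiff(names(factors), f),
                                        collapse = " + "),
                                  if (length(factors) > 1L) "+" else "",
                                  "(1 | ward)"))
      red <- tryCatch(suppressWarnings(
        lme4::glmer(red_fml, data = dat, family = binomial,
                    control = lme4::glmerControl(
                      check.conv.singular = "ignore"))),
        error = function(e) NULL)
      if (is.null(red)) {
        lrt_dt <- rbind(lrt_dt, data.table(factor = f, df = NA_integer_,
                                           chisq = NA_real_, p_lrt = NA_real_))
        next
      }
      stat <- as.numeric(2 * (logLik(fit) - logLik(red)))
      df <- attr(logLik(fit), "df") - attr(logLik(red), "df")
      lrt_dt <- rbind(lrt_dt, data.table(
        factor = f, df = as.integer(df), chisq = max(stat, 0),
        p_lrt = pchisq(max(stat, 0), df = df, lower.tail = FALSE)))
    }
  }
  structure(list(outcome = outcome, coefficients = co[], lrt = lrt_dt,
                 ranef_var = as.numeric(lme4::VarCorr(fit)$ward[1L]),
                 n_obs = nrow(dat), converged = conv, separation = sep,
                 logLik = as.numeric(logLik(fit)), model = fit,
                 factors = factors),
            class = "cpi_glmm")
}

stars_for <- function(p) {
  fifelse(is.na(p), "",
          fifelse(p < 0.001, "***",
                  fifelse(p < 0.01, "**",
                          fifelse(p < 0.05, "*",
                                  fifelse(p < 0.1, ".", "")))))
}

#' @export
print.cpi_glmm <- function(x, ...) {
  cat(sprintf("<cpi_glmm> outcome %s, n = %d, ward variance = %s%s\n",
              x$outcome, x$n_obs,
              format(x$ranef_var, digits = 3),
              if (x$converged) "" else " [convergence warning]"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (nrow(x$coefficients)) {
    show <- x$coefficients[!is.na(factor),
                           .(factor, level, or = round(or, 2),
                             ci = sprintf("(%.2f-%.2f)", ci_lo, ci_hi),
                             stars)]
    print(show, nrows = 50L)
  }
  if (nrow(x$lrt)) {
    cat("Likelihood-ratio tests:\n")
    print(x$lrt)
  }
  if (length(x$separation))
    cat("Possible complete separation:", paste(x$separation, collapse = ", "),
        "\n")
  invisible(x)
}

#' Likelihood-ratio test for one factor
#'
#' Refits the model without `factor` and compares twice the
#' log-likelihood difference to a chi-squared distribution with
#' `levels - 1` degrees of freedom.
#'
#' @param fit A `cpi_glmm` from [fit_glmm()] (fitted with `lrt` either
#'   value).
#' @param factor Name of the factor to drop.
#' @return Scalar p-value (NA when the reduced fit fails).
#' @export
lrt_factor <- function(fit, factor) {
  stopifnot(inherits(fit, "cpi_glmm"))
  if (nrow(fit$lrt) && factor %in% fit$lrt$factor)
    return(fit$lrt[fit$lrt$factor == factor, ]$p_lrt)
  if (is.null(fit$model)) return(NA_real_)
  red_terms <- setdiff(names(fit$factors), factor)
  red_fml <- as.formula(paste(fit$outcome, "~",
                              paste(red_terms, collapse = " + "),
                              if (length(red_terms)) "+" else "",
                              "(1 | ward)"))
  red <- tryCatch(suppressWarnings(
    lme4::glmer(red_fml, data = fit$model@frame, family = binomial,
                control = lme4::glmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(red)) return(NA_real_)
  stat <- max(as.numeric(2 * (logLik(fit$model) - logLik(red))), 0)
  df <- attr(logLik(fit$model), "df") - attr(logLik(red), "df")
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Threshold sensitivity analysis
#'
#' Re-dichotomizes the outcome table at every `k` in `k_list` and refits
#' the mixed model, collecting the per-level odds ratios so their
#' stability across thresholds can be inspected.
#'
#' @param table Outcome table ([build_outcome_table()]).
#' @param outcome `"high_freq"` or `"high_dur"`.
#' @param factors Named list `factor -> reference`; default per
#'   population.
#' @param k_list Integer thresholds to sweep.
#' @return `data.table` stacking the coefficient tables with columns
#'   `k`, `prop_high`, `converged` added; failed fits are recorded with
#'   NA estimates.
#' @export
sensitivity_analysis <- function(table, outcome = c("high_freq", "high_dur"),
                                 factors = NULL, k_list = 0:3) {
  outcome <- match.arg(outcome)
  out <- vector("list", length(k_list))
  for (i in seq_along(k_list)) {
    kk <- k_list[i]
    dk <- dichotomize(table, kk)
    prop <- mean(dk[[outcome]])
    fit <- tryCatch(fit_glmm(dk, outcome, factors = factors, lrt = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || nrow(fit$coefficients) == 0L) {
      out[[i]] <- data.table(k = kk, prop_high = prop, factor = NA_character_,
                             level = NA_character_, or = NA_real_,
                             ci_lo = NA_real_, ci_hi = NA_real_,
                             converged = FALSE)
    } else {
      co <- fit$coefficients[!is.na(factor),
                             .(factor, level, or, ci_lo, ci_hi)]
      co[, `:=`(k = kk, prop_high = prop, converged = fit$converged)]
      out[[i]] <- co
    }
  }
  rbindlist(out, use.names = TRUE, fill = TRUE)
}

#' Simulate person-day outcome tables from the model class
#'
#' Draws a binary-outcome table directly from the logistic
#' ward-random-intercept model: covariates sampled from given level
#' probabilities, ward intercepts from `N(0, ward_sd^2)`, outcome from
#' the implied Bernoulli probability. Used for parameter-recovery and
#' type-I-error experiments.
#'
#' @param n Number of person-days.
#' @param factors Named list: each element a named probability vector
#'   over the factor's levels (first level = reference).
#' @param beta Named list mirroring `factors`: log-odds per non-reference
#'   level (missing levels mean 0).
#' @param intercept Intercept on the log-odds scale.
#' @param ward_sd Random-intercept standard deviation.
#' @param n_wards Number of wards.
#' @param seed Integer seed.
#' @return A dichotomized-style table with `ward`, the factors and a
#'   `y` column, carrying `"truth"` (the generating parameters).
#' @export
simulate_glmm_table <- function(n, factors, beta, intercept = -1.5,
                                ward_sd = 0.5, n_wards = 5L, seed = 1L) {
  set.seed(seed)
  wards <- paste0("W", seq_len(n_wards))
  dat <- data.table(ward = sample(wards, n, replace = TRUE))
  eta <- rep(intercept, n)
  u <- rnorm(n_wards, 0, ward_sd)
  eta <- eta + u[match(dat$ward, wards)]
  for (f in names(factors)) {
    p <- factors[[f]]
    lev <- names(p)
    set(dat, j = f, value = factor(sample(lev, n, replace = TRUE, prob = p),
                                   levels = lev))
    b <- setNames(rep(0, length(lev)), lev)
    if (!is.null(beta[[f]])) b[names(beta[[f]])] <- beta[[f]]
    eta <- eta + b[as.character(dat[[f]])]
  }
  set(dat, j = "y", value = rbinom(n, 1L, plogis(eta)))
  setattr(dat, "truth", list(intercept = intercept, beta = beta,
                             ward_sd = ward_sd, u = u))
  dat[]
}
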
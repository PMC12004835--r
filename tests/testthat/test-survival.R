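test_that("survival records censor survivors and map causes by prefix", {
  subjects <- data.frame(subject_id = c("a", "b", "c", "d"),
                         cohort = c("west", "west", "west", "late"))
  deaths <- data.frame(subject_id = c("b", "c"), time = c(3.5, 12),
                       icd10 = c("I21", "C34"))
  rec <- build_survival_records(subjects, deaths, followup_end = 20)
  expect_identical(rec$time, c(20, 3.5, 12, 20))
  expect_identical(rec$event, c(0L, 1L, 1L, 0L))
  expect_identical(rec$cause, c(NA, "cardiovascular", "lung_cancer", NA))

  # unmapped codes fall into the other-cause bucket
  rec2 <- build_survival_records(
    subjects[1:2, ], data.frame(subject_id = "b", time = 1, icd10 = "G30"), 20)
  expect_identical(rec2$cause[2], "other")

  # short-register cohorts are excluded with a recorded count
  expect_message(
    rec3 <- build_survival_records(subjects, deaths, 20,
                                   cohort_followup = c(west = 21, late = 1),
                                   min_followup = 2),
    "excluding 1 subject")
  expect_identical(attr(rec3, "n_excluded"), 1L)
  expect_false("d" %in% rec3$subject_id)

  expect_error(build_survival_records(
    subjects, data.frame(subject_id = "a", time = -1, icd10 = "I21"), 20),
    "before baseline")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  rec <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 1L))
  km <- km_curve(rec, rep("g", 3))
  s <- km$curve[km$curve$time %in% 1:3, "surv"]
  expect_equal(s, c(2 / 3, 1 / 3, 0))

  # all censored: survival stays at 1
  km1 <- km_curve(data.frame(time = c(2, 4), event = c(0L, 0L)), rep("g", 2))
  expect_true(all(km1$curve$surv == 1))

  # without censoring KM equals the empirical survival function
  set.seed(3)
  t <- round(rexp(200, 0.2), 3)
  km2 <- km_curve(data.frame(time = t, event = 1L), rep("g", 200))
  emp <- vapply(km2$curve$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$curve$surv, emp, tolerance = 1e-12)

  expect_warning(
    km_curve(data.frame(time = 1, event = 1L), factor("a", levels = c("a", "b"))),
    "empty group")
})

test_that("the events-per-covariate guard is boundary-exact", {
  expect_true(epv_guard(120, 12))
  expect_false(epv_guard(119, 12))
  expect_false(epv_guard(0, 1))
  expect_true(epv_guard(0, 0))
})

test_that("Cox coefficients match a brute-force partial likelihood", {
  # 6 subjects, one binary exposure, distinct times (no ties)
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1L, 1L, 0L, 1L, 1L, 0L),
                  group = factor(c("ref", "exp", "ref", "exp", "ref", "exp"),
                                 levels = c("ref", "exp")))
  fit <- fit_cox(d, "group")
  x <- as.integer(d$group == "exp")
  nll <- function(beta) {
    out <- 0
    for (i in which(d$event == 1L)) {
      risk <- which(d$time >= d$time[i])
      out <- out - (beta * x[i] - log(sum(exp(beta * x[risk]))))
    }
    out
  }
  brute <- stats::optimize(nll, c(-5, 5), tol = 1e-10)$minimum
  expect_equal(unname(fit$coef[1]), brute, tolerance = 1e-6)
  expect_identical(fit$n_events, 4L)
})

test_that("null simulated data give a CI containing 1", {
  set.seed(41)
  n <- 4000
  d <- data.frame(time = rexp(n, 0.1), event = 1L,
                  group = factor(sample(c("a", "b"), n, TRUE),
                                 levels = c("a", "b")))
  cens <- d$time > 8
  d$event[cens] <- 0L
  d$time[cens] <- 8
  fit <- fit_cox(d, "group")
  pe <- rubin_pool(fit$coef[1], fit$var[1])
  expect_lt(pe$hr_low, 1)
  expect_gt(pe$hr_high, 1)
})

test_that("Fine-Gray reduces to Cox without competing events", {
  set.seed(17)
  n <- 500
  d <- data.frame(time = rexp(n, 0.2), event = 1L,
                  group = factor(sample(c("a", "b"), n, TRUE)),
                  age = rnorm(n, 50, 10))
  cens <- d$time > 6
  d$event[cens] <- 0L
  d$time[cens] <- 6
  d$cause <- ifelse(d$event == 1L, "cardiovascular", NA)
  fg <- fit_fine_gray(d, "cardiovascular", "group", "age")
  cx <- fit_cox(d, "group", "age")
  expect_equal(fg$coef, cx$coef, tolerance = 1e-6)
  expect_equal(fg$var, cx$var, tolerance = 1e-6)

  expect_error(fit_fine_gray(d, "respiratory", "group"), "no events")
})

test_that("Fine-Gray agrees with an independent competing-risks fitter", {
  skip_if_not_installed("cmprsk")
  set.seed(29)
  n <- 800
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.15 * exp(0.5 * x))
  t2 <- rexp(n, 0.10)
  cens <- runif(n, 0, 12)
  t <- pmin(t1, t2, cens)
  status <- ifelse(t == cens, 0L, ifelse(t == t1, 1L, 2L))
  d <- data.frame(time = t, event = as.integer(status > 0L),
                  cause = ifelse(status == 1L, "target",
                                 ifelse(status == 2L, "other_cause", NA)),
                  group = factor(ifelse(x == 1, "exp", "ref"),
                                 levels = c("ref", "exp")))
  fg <- fit_fine_gray(d, "target", "group")
  crr <- cmprsk::crr(t, status, cov1 = matrix(x), failcode = 1, cencode = 0)
  expect_equal(unname(fg$coef[1]), unname(crr$coef), tolerance = 1e-4)
})

test_that("cumulative incidence functions sum to at most one", {
  set.seed(37)
  n <- 600
  t1 <- rexp(n, 0.2); t2 <- rexp(n, 0.15); cens <- runif(n, 0, 10)
  t <- pmin(t1, t2, cens)
  d <- data.frame(time = t, event = as.integer(t < cens),
                  cause = ifelse(t == t1, "a", "b"))
  d$cause[d$event == 0L] <- NA
  cif <- cif_estimate(d)
  expect_true(all(rowSums(cif[, c("a", "b")]) <= 1 + 1e-12))
  expect_true(all(diff(cif$a) >= -1e-12))
})

test_that("proportionality checks calibrate near nominal and detect drift", {
  # type-I error of the zero-slope score test under proportional hazards
  set.seed(53)
  rej <- vapply(1:100, function(i) {
    n <- 300
    d <- data.frame(time = rexp(n, 0.2), event = 1L,
                    group = factor(sample(c("a", "b"), n, TRUE)))
    cens <- d$time > 8
    d$event[cens] <- 0L; d$time[cens] <- 8
    zp <- check_proportionality(fit_cox(d, "group"))
    zp$table$p[1] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12) # 3-sigma above the nominal 5% at 100 reps
  expect_gt(mean(rej), 0)    # the test is not degenerate

  # a strongly time-varying planted effect is detected
  set.seed(59)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  r1 <- exp(1.5 * x); r2 <- exp(-1.5 * x) # effect flips sign at t = 0.5
  u <- rexp(n, 1)
  t <- ifelse(u / r1 < 0.5, u / r1, 0.5 + (u - 0.5 * r1) / r2)
  d <- data.frame(time = t, event = 1L,
                  group = factor(ifelse(x == 1, "exp", "ref"),
                                 levels = c("ref", "exp")))
  zp <- check_proportionality(fit_cox(d, "group"))
  expect_lt(zp$table$p[1], 0.05)

  # unscaled Schoenfeld residuals solve the score equation: they sum to ~0
  res <- residuals(fit_cox(d, "group")$engine, type = "schoenfeld")
  expect_lt(abs(sum(res)), 1e-6)
})

test_that("Rubin's rules match the closed form", {
  pe <- rubin_pool(c(0.2, 0.4), c(0.01, 0.01))
  expect_equal(pe$estimate, 0.3)
  expect_equal(pe$W, 0.01)
  expect_equal(pe$B, 0.02)
  expect_equal(pe$T, 0.04)
  expect_lt(pe$ci_low, pe$estimate)
  expect_gt(pe$ci_high, pe$estimate)
  expect_gte(pe$T, pe$W)

  one <- rubin_pool(0.5, 0.02)
  expect_equal(one$estimate, 0.5)
  expect_equal(one$T, 0.02)

  same <- rubin_pool(rep(0.3, 4), rep(0.01, 4))
  expect_equal(same$B, 0)
  expect_equal(same$T, same$W)
  expect_error(rubin_pool(numeric(0), numeric(0)), "no estimates")

  # Barnard-Rubin df shrink with finite complete-data df
  br <- rubin_pool(c(0.2, 0.4), c(0.01, 0.01), df_com = 50)
  expect_lt(br$df, rubin_pool(c(0.2, 0.4), c(0.01, 0.01))$df)
})

test_that("under-powered analyses are skipped and logged, never fitted", {
  set.seed(61)
  n <- 300
  d <- data.frame(
    time = rexp(n, 0.05), event = 0L, cause = NA_character_,
    group = factor(sample(c("asymptomatic", "cluster1"), n, TRUE),
                   levels = c("asymptomatic", "cluster1")),
    age = rnorm(n, 50, 10), sex = sample(c("f", "m"), n, TRUE))
  # exactly 8 events: below 10 x 1 covariate for the crude model
  d$event[1:8] <- 1L
  d$cause[1:8] <- "cardiovascular"
  d$time <- pmin(d$time, 15)
  out <- run_mortality_analysis(list(d), confounders = c("age", "sex"),
                                outcomes = "all_cause")
  expect_identical(nrow(out$results), 0L)
  expect_identical(nrow(out$skipped), 2L)
  expect_match(out$skipped$reason[1], "8 events < 10 x")
})

test_that("follow-up truncation censors administratively at the horizon", {
  set.seed(67)
  n <- 2500
  d <- data.frame(
    time = rexp(n, 0.15), event = 1L,
    group = factor(sample(c("asymptomatic", "cluster1"), n, TRUE),
                   levels = c("asymptomatic", "cluster1")),
    age = rnorm(n, 50, 10))
  d$cause <- "other"
  over <- d$time > 18
  d$event[over] <- 0L; d$time[over] <- 18; d$cause[over] <- NA
  out <- run_mortality_analysis(list(d), confounders = "age",
                                outcomes = "all_cause",
                                strata = c("overall", "followup5"),
                                adjustments = "adjusted")
  expect_setequal(unique(out$results$stratum), c("overall", "followup<=5"))
  # truncated events can only be those occurring before the horizon
  n5 <- out$results$n_events[out$results$stratum == "followup<=5"][1]
  expect_equal(n5, sum(d$time <= 5 & d$event == 1L))
})
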
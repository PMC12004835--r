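test_that("generation is deterministic and validates its configuration", {
  cfg <- generator_config(n_subjects = 300, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$data, b$table$data)
  expect_identical(a$truth, b$truth)

  expect_error(generator_config(mixing = c(0.5, 0.4)), "sum to 1")
  expect_error(generator_config(asymptomatic_fraction = 1.2), "\\[0, 1\\)")
  prof <- default_symptom_profiles()
  prof[1, 1] <- 1.5
  expect_error(generator_config(symptom_profiles = prof), "\\[0, 1\\]")
})

test_that("asymptomatic subjects are all-zero and their share is calibrated", {
  cfg <- generator_config(n_subjects = 1000, asymptomatic_fraction = 0.4,
                          seed = 7)
  gen <- generate_cohort(cfg)
  asym <- gen$truth$cluster == 0L
  items <- as.matrix(gen$table$data[asym, default_symptom_items()])
  expect_true(all(items == 0L))
  # binomial 3-sigma band around 400
  expect_lt(abs(sum(asym) - 400), 3 * sqrt(1000 * 0.4 * 0.6))
})

test_that("empirical cluster shares converge to the published mixing", {
  cfg <- generator_config(n_subjects = 20000, seed = 5)
  gen <- generate_cohort(cfg)
  shares <- tabulate(gen$truth$cluster, 5) / sum(gen$truth$cluster > 0)
  target <- c(0.303, 0.107, 0.047, 0.066, 0.041) / 0.564
  n_sym <- sum(gen$truth$cluster > 0)
  for (c in 1:5) {
    se <- sqrt(target[c] * (1 - target[c]) / n_sym)
    expect_lt(abs(shares[c] - target[c]), 3 * se)
  }
  expect_true(all(gen$truth$subject_id == gen$table$data$subject_id))
})

test_that("missingness injection hits the configured rate and spares registers", {
  tab <- generate_cohort(generator_config(n_subjects = 1000, seed = 2))$table
  expect_identical(inject_missingness(tab, "MCAR", 0), tab)

  out <- inject_missingness(tab, "MCAR", 0.112, seed = 3)
  sv <- survey_vars(out$schema)
  frac <- mean(is.na(out$data[, sv]))
  ncell <- 1000 * length(sv)
  expect_lt(abs(frac - 0.112), 3 * sqrt(0.112 * 0.888 / ncell))

  # register variables are refused
  expect_error(
    inject_missingness(toy_cohort(), "MCAR", 0.1, vars = "cci"),
    "non-survey variable")
})

test_that("MAR missingness reflects per-cohort rates", {
  tab <- generate_cohort(generator_config(n_subjects = 4000, seed = 8))$table
  out <- inject_missingness(tab, "MAR", 0.1, seed = 4,
                            cohort_rates = c(west = 0.05, north = 0.2))
  items <- default_symptom_items()
  by_cohort <- vapply(split(out$data[items], out$data$cohort),
                      function(d) mean(is.na(as.matrix(d))), numeric(1))
  expect_lt(abs(by_cohort[["west"]] - 0.05), 0.02)
  expect_lt(abs(by_cohort[["north"]] - 0.2), 0.03)
  # conditioning variables stay observed
  expect_false(anyNA(out$data$cohort))
  expect_false(anyNA(out$data$age))
})

test_that("survival times follow the configured exponential model", {
  n <- 20000
  truth <- data.frame(subject_id = as.character(1:n), cluster = 0L)
  covs <- data.frame(age = rep(48, n), sex = "female", smoking = "never")
  sm <- default_survival_model()
  # null effects, single effective cause, no censoring horizon
  sm$cluster_loghr[] <- 0
  h <- sum(unlist(sm$baseline_hazards)) # min of exponentials ~ Exp(sum h)
  sm$admin_end <- Inf
  sv <- generate_survival(truth, covs, sm, seed = 21)
  expect_true(all(sv$time >= 0))
  expect_equal(mean(sv$time), 1 / h, tolerance = 0.05)
  expect_true(all(sv$event == 1L))

  sm$admin_end <- 0
  sv0 <- generate_survival(truth, covs, sm, seed = 21)
  expect_true(all(sv0$event == 0L))
  expect_true(all(sv0$time == 0))

  sm$baseline_hazards["cardiovascular"] <- -1
  expect_error(generate_survival(truth, covs, sm, seed = 1), "positive")
})

test_that("a cluster log-HR of log(2) doubles the rare-event cause rate", {
  n <- 40000
  truth <- data.frame(subject_id = as.character(1:n),
                      cluster = rep(c(0L, 1L), each = n / 2))
  covs <- data.frame(age = rep(48, n), sex = "female", smoking = "never")
  sm <- default_survival_model(1)
  sm$baseline_hazards <- c(cardiovascular = 0.001, respiratory = 0.001,
                           lung_cancer = 0.001, other = 0.001)
  sm$cluster_loghr <- matrix(c(log(2), 0, 0, 0), 1, 4,
                             dimnames = list(NULL, names(sm$baseline_hazards)))
  sm$admin_end <- 2 # short horizon keeps events rare
  sv <- generate_survival(truth, covs, sm, seed = 31)
  p_ref <- mean(sv$event == 1L & sv$cause == "cardiovascular" &
                  truth$cluster == 0L) / 0.5
  p_cl <- mean(sv$event == 1L & sv$cause == "cardiovascular" &
                 truth$cluster == 1L) / 0.5
  expect_equal(p_cl / p_ref, 2, tolerance = 0.25)
})

test_that("ICD histories are reproducible, rate-driven and mostly CCI-free", {
  cfg <- generator_config(n_subjects = 2000, seed = 6)
  subjects <- data.frame(subject_id = sprintf("S%04d", 1:2000))
  a <- generate_icd_histories(cfg, subjects, seed = 13)
  b <- generate_icd_histories(cfg, subjects, seed = 13)
  expect_identical(a, b)
  expect_true(all(valid_icd10 <- grepl("^[A-Z][0-9]{2}", a$icd10)))
  yrs <- as.integer(format(a$date, "%Y"))
  expect_true(all(yrs >= 2008 - 11 & yrs <= 2008))

  cfg0 <- cfg
  cfg0$comorbidity_model$cci_rate <- 0
  cfg0$comorbidity_model$other_rate <- 0
  expect_identical(nrow(generate_icd_histories(cfg0, subjects, seed = 1)), 0L)

  # with the default rate ~93% of subjects carry no CCI-relevant codes
  scores <- cci_scores(a, subjects$subject_id, index_year = 2008)
  p0 <- mean(scores == 0)
  expect_lt(abs(p0 - 0.93), 3 * sqrt(0.93 * 0.07 / 2000) + 0.01)
})
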
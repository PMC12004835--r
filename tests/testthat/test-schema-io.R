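test_that("schema construction enforces the variable invariants", {
  expect_error(variable_spec("x", "binary", levels = c(1, 2)), "levels \\{0, 1\\}")
  expect_error(variable_spec("x", "ordinal", levels = 0), ">= 2 ordered levels")
  expect_error(variable_spec("x", "continuous", role = "symptom"),
               "binary or ordinal")
  expect_error(resp_schema(variable_spec("a", "binary"),
                           variable_spec("a", "binary")), "duplicate")
  sch <- toy_schema()
  expect_setequal(schema_vars(sch, role = "symptom"),
                  c("wheeze", "cough", "dyspnea", "rhinitis_grade"))
  expect_false("cci" %in% survey_vars(sch))
})

test_that("cohort CSV and schema files round-trip cell-for-cell", {
  tab <- toy_cohort(7)
  tab$data$wheeze[3] <- NA # a missing survey cell survives the trip
  tab <- cohort_table(tab$data, tab$schema)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f, toy_schema())
  expect_identical(back$data, tab$data)

  fs <- withr::local_tempfile(fileext = ".csv")
  write_schema(toy_schema(), fs)
  sch2 <- read_schema(fs)
  expect_identical(names(sch2), names(toy_schema()))
  expect_identical(schema_levels(sch2, "rhinitis_grade"), 0:3)
})

test_that("reading rejects unknown columns, missing columns and bad levels", {
  tab <- toy_cohort(3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, f)

  df <- tab$data
  df$rhinitis_grade[2] <- 7L
  expect_error(cohort_table(df, toy_schema()), "invalid level '7'.*T002")

  df2 <- tab$data
  df2$extra <- 1
  expect_error(cohort_table(df2, toy_schema()), "not declared in schema")
  expect_error(cohort_table(tab$data[, -2], toy_schema()), "absent from data")

  df3 <- tab$data
  df3$cci[1] <- NA
  expect_error(cohort_table(df3, toy_schema()), "register variable")
})

test_that("highest-affirmative composite matches enumeration of all triples", {
  # independent oracle: position of the last 1, scanned by hand over
  # the 8 binary triples
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  expected <- apply(combos, 1, function(r) {
    out <- 0L
    for (i in 1:3) if (r[i] == 1L) out <- i
    out
  })
  sch <- resp_schema(
    variable_spec("a", "binary", "symptom"),
    variable_spec("b", "binary", "symptom"),
    variable_spec("c", "binary", "symptom"),
    variable_spec("age", "continuous", "background")
  )
  tab <- cohort_table(cbind(data.frame(subject_id = sprintf("S%d", 1:8)),
                            combos, age = 50), sch)
  out <- build_composites(tab, composite_rule("sev", c("a", "b", "c")))
  expect_identical(out$data$sev, as.integer(expected))
  expect_identical(schema_levels(out$schema, "sev"), 0:3)
  # sources dropped from the symptom role, non-symptom columns untouched
  expect_setequal(schema_vars(out$schema, role = "symptom"), "sev")
  expect_identical(out$data$age, tab$data$age)
  expect_identical(out$data$subject_id, tab$data$subject_id)
})

test_that("composites propagate all-missing and reject partial missingness", {
  sch <- resp_schema(variable_spec("a", "binary", "symptom"),
                     variable_spec("b", "binary", "symptom"))
  tab <- cohort_table(data.frame(subject_id = c("x", "y"),
                                 a = c(NA, 0L), b = c(NA, 1L)), sch)
  out <- build_composites(tab, composite_rule("s", c("a", "b")))
  expect_identical(out$data$s, c(NA, 2L))

  tab2 <- cohort_table(data.frame(subject_id = c("x"), a = NA, b = 1L), sch)
  expect_error(build_composites(tab2, composite_rule("s", c("a", "b"))),
               "partially missing")
  expect_error(build_composites(tab, composite_rule("s", c("a", "nope"))),
               "unknown variable")
})

test_that("symptom counting follows the affirmative rule and range", {
  sch <- toy_schema()
  d <- data.frame(subject_id = c("p", "q", "r"),
                  wheeze = c(0L, 1L, 1L), cough = c(0L, 1L, 1L),
                  dyspnea = c(0L, 1L, 1L), rhinitis_grade = c(0L, 2L, 0L),
                  age = 50, sex = "female", cohort = "west", cci = 0L)
  counts <- count_symptoms(cohort_table(d, sch))
  expect_identical(unname(counts), c(0L, 4L, 3L))

  # a full 31-item generator row affirmative everywhere counts 31
  cfg <- generator_config(n_subjects = 10, seed = 1)
  gen <- generate_cohort(cfg)
  gen$table$data[1, default_symptom_items()] <- 1L
  expect_identical(unname(count_symptoms(gen$table)[1]), 31L)

  d$wheeze[1] <- NA
  expect_error(count_symptoms(cohort_table(d, sch)), "impute")
})

test_that("symptom counting is monotone in 0 -> 1 flips", {
  tab <- toy_cohort(20, seed = 4)
  base <- count_symptoms(tab)
  for (v in c("wheeze", "cough", "dyspnea")) {
    bumped <- tab
    bumped$data[[v]] <- 1L
    expect_true(all(count_symptoms(bumped) >= base))
  }
})

test_that("eligibility split partitions, warns when degenerate, idempotent", {
  tab <- toy_cohort(30, seed = 2)
  sp <- eligibility_split(tab)
  expect_equal(n_subjects(sp$symptomatic) + n_subjects(sp$asymptomatic),
               n_subjects(tab))
  expect_length(intersect(sp$symptomatic$data$subject_id,
                          sp$asymptomatic$data$subject_id), 0)
  expect_true(all(count_symptoms(sp$symptomatic) >= 1))
  expect_true(all(count_symptoms(sp$asymptomatic) == 0))

  again <- suppressWarnings(eligibility_split(sp$symptomatic))
  expect_identical(again$symptomatic$data, sp$symptomatic$data)
  expect_warning(eligibility_split(sp$symptomatic), "reference group is empty")
})
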
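# Shared fixtures: everything is built in code at test time.

# small mixed schema: 3 binary symptoms, 1 ordinal symptom,
# background covariates, 1 register variable
toy_schema <- function() {
  resp_schema(
    variable_spec("wheeze", "binary", "symptom"),
    variable_spec("cough", "binary", "symptom"),
    variable_spec("dyspnea", "binary", "symptom"),
    variable_spec("rhinitis_grade", "ordinal", "symptom", levels = 0:3),
    variable_spec("age", "continuous", "background"),
    variable_spec("sex", "nominal", "background", c("female", "male")),
    variable_spec("cohort", "nominal", "background", c("west", "north")),
    variable_spec("cci", "ordinal", "register", levels = 0:9)
  )
}

toy_cohort <- function(n = 12, seed = 1) {
  set.seed(seed)
  cohort_table(data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    wheeze = sample(0:1, n, TRUE),
    cough = sample(0:1, n, TRUE),
    dyspnea = sample(0:1, n, TRUE),
    rhinitis_grade = sample(0:3, n, TRUE),
    age = round(runif(n, 20, 70), 1),
    sex = sample(c("female", "male"), n, TRUE),
    cohort = sample(c("west", "north"), n, TRUE),
    cci = sample(0:3, n, TRUE),
    stringsAsFactors = FALSE
  ), toy_schema())
}

# five block-separated Bernoulli profiles over the 31 default items:
# each cluster owns a 6-item block at 0.9 against a 0.05 background, so
# every cluster pair differs by 0.85 on 12 items (total-variation
# separation of the joint item distributions well above 0.5)
strong_profiles <- function() {
  items <- default_symptom_items()
  p <- matrix(0.05, 5, length(items),
              dimnames = list(paste0("cluster", 1:5), items))
  blocks <- split(1:30, rep(1:5, each = 6))
  for (c in 1:5) p[c, blocks[[c]]] <- 0.9
  p
}

# generated cohort in the strong-separation regime, split for clustering
make_separated_cohort <- function(n = 5000, seed = 1) {
  cfg <- generator_config(n_subjects = n, symptom_profiles = strong_profiles(),
                          seed = seed)
  gen <- generate_cohort(cfg)
  sp <- eligibility_split(gen$table)
  truth <- gen$truth$cluster[match(sp$symptomatic$data$subject_id,
                                   gen$truth$subject_id)]
  list(table = sp$symptomatic, truth = truth, full = gen)
}

# brute-force mixed distance matrix via point_point_distance (small n only)
brute_distance_matrix <- function(table, vars = NULL) {
  n <- n_subjects(table)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- point_point_distance(
        table$data[i, ], table$data[j, ], table$schema, vars = vars)
    }
  }
  D
}
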
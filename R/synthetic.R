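#' Default symptom item names
#'
#' Thirty-one binary questionnaire items covering the five respiratory
#' symptom domains used for clustering: wheezing, dyspnea, coughing,
#' night-time symptoms, and nasal/sinus symptoms.
#'
#' @return Character vector of 31 item names.
#' @export
default_symptom_items <- function() {
  c(
    # wheezing
    "wheeze_12m", "wheeze_recurrent", "wheeze_with_breathlessness",
    "wheeze_without_cold", "tight_chest_12m",
    # dyspnea
    "dyspnea_exertion", "dyspnea_rest", "dyspnea_attack_cold_dust",
    "dyspnea_attack_pollen_fur", "dyspnea_attack_exercise",
    "dyspnea_attack_painkillers",
    # coughing
    "cough_morning", "cough_daytime", "productive_cough",
    "productive_cough_chronic", "cough_attack_12m",
    # night-time
    "night_cough_waking", "night_tight_chest", "night_dyspnea_waking",
    "night_wheeze",
    # nasal / sinus
    "rhinitis_ever", "rhinitis_12m", "rhinitis_5days_week",
    "rhinitis_5weeks", "nasal_obstruction_recurrent",
    "rhinorrhea_recurrent", "nasal_symptoms_13weeks", "sneezing_attacks",
    "itchy_eyes_nose", "sinusitis_12m", "hoarseness"
  )
}

#' Default per-cluster symptom profiles
#'
#' Bernoulli probability of each of the 31 binary items within each of the
#' five planted symptom clusters.  The profiles are loosely calibrated to
#' the published cluster characterisations: a low-symptomatic cluster, an
#' allergic-nasal cluster, an allergic-nasal + wheeze + dyspnea cluster, a
#' wheeze + dyspnea cluster, and a recurrent-productive-cough + wheeze
#' cluster.  Asymptomatic subjects carry all-zero items and are not part
#' of this matrix.
#'
#' @return 5 x 31 numeric matrix, rows = clusters, columns = items.
#' @export
default_symptom_profiles <- function() {
  items <- default_symptom_items()
  p <- matrix(0.05, nrow = 5, ncol = length(items),
              dimnames = list(paste0("cluster", 1:5), items))
  # cluster 1: low-symptomatic
  p[1, ] <- 0.06
  p[1, "dyspnea_attack_cold_dust"] <- 0.37
  p[1, "night_cough_waking"] <- 0.30
  p[1, "nasal_obstruction_recurrent"] <- 0.20
  p[1, "rhinorrhea_recurrent"] <- 0.20
  p[1, c("cough_morning", "rhinitis_ever", "sneezing_attacks")] <- 0.15
  # cluster 2: allergic nasal symptoms
  p[2, ] <- 0.05
  p[2, c("rhinitis_ever", "rhinitis_12m")] <- c(0.95, 0.85)
  p[2, c("rhinitis_5days_week", "rhinitis_5weeks")] <- c(0.53, 0.44)
  p[2, c("sneezing_attacks", "itchy_eyes_nose")] <- c(0.70, 0.65)
  p[2, "dyspnea_attack_pollen_fur"] <- 0.43
  p[2, "dyspnea_attack_cold_dust"] <- 0.30
  p[2, c("nasal_obstruction_recurrent", "rhinorrhea_recurrent")] <- 0.35
  # cluster 3: allergic nasal + wheezing + dyspnea attacks
  p[3, ] <- 0.30
  p[3, c("wheeze_12m", "wheeze_recurrent", "wheeze_with_breathlessness",
         "wheeze_without_cold", "tight_chest_12m")] <-
    c(0.94, 0.57, 0.60, 0.55, 0.55)
  p[3, c("dyspnea_exertion", "dyspnea_rest", "dyspnea_attack_cold_dust",
         "dyspnea_attack_pollen_fur", "dyspnea_attack_exercise",
         "dyspnea_attack_painkillers")] <-
    c(0.80, 0.74, 0.85, 0.80, 0.78, 0.25)
  p[3, c("rhinitis_ever", "rhinitis_12m", "rhinitis_5days_week",
         "rhinitis_5weeks", "nasal_obstruction_recurrent",
         "nasal_symptoms_13weeks", "sneezing_attacks",
         "itchy_eyes_nose")] <-
    c(0.98, 0.90, 0.55, 0.48, 0.52, 0.44, 0.75, 0.70)
  # cluster 4: wheezing and dyspnea attacks
  p[4, ] <- 0.15
  p[4, c("wheeze_12m", "wheeze_recurrent", "wheeze_with_breathlessness",
         "wheeze_without_cold", "tight_chest_12m")] <-
    c(0.98, 0.55, 0.50, 0.45, 0.45)
  p[4, c("dyspnea_exertion", "dyspnea_attack_cold_dust",
         "dyspnea_attack_exercise")] <- c(0.60, 0.60, 0.45)
  p[4, c("night_cough_waking", "night_tight_chest", "night_dyspnea_waking",
         "night_wheeze")] <- c(0.50, 0.40, 0.35, 0.40)
  # cluster 5: recurrent productive cough and wheezing
  p[5, ] <- 0.15
  p[5, c("cough_morning", "cough_daytime", "productive_cough",
         "productive_cough_chronic", "cough_attack_12m")] <-
    c(0.80, 0.70, 0.85, 0.72, 0.60)
  p[5, c("wheeze_12m", "wheeze_recurrent")] <- c(0.85, 0.50)
  p[5, "dyspnea_attack_cold_dust"] <- 0.75
  p[5, c("night_cough_waking", "night_tight_chest", "night_dyspnea_waking",
         "night_wheeze")] <- c(0.77, 0.55, 0.50, 0.55)
  p[5, "hoarseness"] <- 0.40
  p
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort: sample size, the
#' asymptomatic fraction, planted cluster mixing proportions, per-cluster
#' symptom profiles, covariate marginals, the comorbidity event model, the
#' competing-risks survival model, and the survey missingness mechanism.
#'
#' Defaults reproduce the study conditions: five clusters with shares
#' 30.3/10.7/4.7/6.6/4.1 percent of the full cohort (56.4 percent
#' symptomatic in total), 53 percent women, age 48 +/- 16 years, smoking
#' 14 percent current / 23 percent former, survey missingness 11.2
#' percent, about 93 percent of subjects with no comorbidity-relevant
#' specialist-care codes, and administrative end of follow-up at 21 years.
#'
#' @param n_subjects Number of subjects.
#' @param asymptomatic_fraction Proportion with no respiratory symptoms.
#' @param mixing Cluster proportions among symptomatic subjects (sums to 1).
#' @param symptom_profiles Clusters x items probability matrix.
#' @param covariate_model,comorbidity_model,survival_model,missingness
#'   Sub-model parameter lists; see defaults in the function body.
#' @param severity_correlation Strength of a shared latent severity factor
#'   inducing within-subject item correlation (0 = conditionally
#'   independent items given cluster, the default).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 5000,
                             asymptomatic_fraction = 0.436,
                             mixing = c(0.303, 0.107, 0.047, 0.066, 0.041) / 0.564,
                             symptom_profiles = default_symptom_profiles(),
                             covariate_model = list(
                               age = list(mean = 48, sd = 16, min = 16, max = 75),
                               bmi = list(mean = 25.5, sd = 4),
                               p_female = 0.53,
                               smoking = c(never = 0.63, former = 0.23, current = 0.14),
                               cohort = c(west = 0.676, north = 0.324),
                               p_occupational_exposure = 0.30,
                               education = c(primary = 0.25, secondary = 0.45,
                                             tertiary = 0.30),
                               ses = c(manual = 0.35, non_manual = 0.45,
                                       self_employed = 0.12, other = 0.08)
                             ),
                             comorbidity_model = list(
                               cci_rate = 0.0726, other_rate = 0.3,
                               lookback_years = 11
                             ),
                             survival_model = default_survival_model(nrow(symptom_profiles)),
                             missingness = list(mechanism = "MCAR", rate = 0.112),
                             severity_correlation = 0,
                             seed = 1L) {
  mixing <- as.numeric(mixing)
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (any(mixing < 0)) stop("mixing proportions must be non-negative")
  if (nrow(symptom_profiles) != length(mixing)) {
    stop("symptom_profiles must have one row per mixing proportion")
  }
  if (any(symptom_profiles < 0 | symptom_profiles > 1)) {
    stop("symptom profile probabilities must lie in [0, 1]")
  }
  if (asymptomatic_fraction < 0 || asymptomatic_fraction >= 1) {
    stop("asymptomatic_fraction must be in [0, 1)")
  }
  if (any(unlist(survival_model$baseline_hazards) <= 0)) {
    stop("baseline hazards must be positive")
  }
  if (comorbidity_model$cci_rate < 0 || comorbidity_model$other_rate < 0) {
    stop("comorbidity rates must be non-negative")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    asymptomatic_fraction = asymptomatic_fraction,
    mixing = mixing,
    n_clusters = length(mixing),
    symptom_profiles = symptom_profiles,
    covariate_model = covariate_model,
    comorbidity_model = comorbidity_model,
    survival_model = survival_model,
    missingness = missingness,
    severity_correlation = severity_correlation,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default competing-risks survival model
#'
#' Cause-specific exponential hazards at the covariate reference (age 48,
#' female, never-smoker, asymptomatic), per-cluster log hazard ratios per
#' cause, covariate log-HRs shared across causes, and a 21-year
#' administrative end of follow-up.  Cluster effects are loosely
#' calibrated to the published adjusted hazard ratios (e.g. all but the
#' allergic-nasal cluster raise all-cause mortality; the wheeze + dyspnea
#' and productive-cough clusters carry the strongest respiratory-mortality
#' effects).
#'
#' @param k Number of symptom clusters.
#' @return List with elements `baseline_hazards`, `cluster_loghr`,
#'   `covariate_loghr`, `admin_end`, `age_center`.
#' @export
default_survival_model <- function(k = 5) {
  cl <- matrix(0, nrow = k, ncol = 4,
               dimnames = list(NULL, c("cardiovascular", "respiratory",
                                       "lung_cancer", "other")))
  if (k == 5) {
    cl[, "cardiovascular"] <- log(c(1.15, 1.00, 1.67, 1.42, 1.40))
    cl[, "respiratory"]    <- log(c(1.30, 1.00, 1.50, 2.02, 1.89))
    cl[, "lung_cancer"]    <- log(c(1.20, 1.00, 1.30, 1.99, 1.50))
    cl[, "other"]          <- log(c(1.10, 0.95, 1.30, 1.15, 1.35))
  }
  list(
    baseline_hazards = c(cardiovascular = 0.0020, respiratory = 0.0003,
                         lung_cancer = 0.0002, other = 0.0025),
    cluster_loghr = cl,
    covariate_loghr = list(age = 0.085, male = 0.40,
                           smoking_current = 0.60, smoking_former = 0.20),
    admin_end = 21,
    age_center = 48
  )
}

#' Default schema for the synthetic cohort
#'
#' @param config A [generator_config()].
#' @return A [resp_schema()] covering the symptom items and background
#'   covariates the generator emits.
#' @export
default_schema <- function(config = generator_config()) {
  cm <- config$covariate_model
  specs <- lapply(colnames(config$symptom_profiles), function(v) {
    variable_spec(v, kind = "binary", role = "symptom")
  })
  specs <- c(specs, list(
    variable_spec("age", "continuous", "background"),
    variable_spec("bmi", "continuous", "background"),
    variable_spec("sex", "nominal", "background", c("female", "male")),
    variable_spec("smoking", "nominal", "background", names(cm$smoking)),
    variable_spec("cohort", "nominal", "background", names(cm$cohort)),
    variable_spec("occupational_exposure", "binary", "background"),
    variable_spec("education", "nominal", "background", names(cm$education)),
    variable_spec("ses", "nominal", "background", names(cm$ses))
  ))
  resp_schema(specs)
}

#' Generate a synthetic cohort with planted symptom clusters
#'
#' Each subject is assigned a latent class: asymptomatic (all symptom
#' items 0) with probability `asymptomatic_fraction`, otherwise one of the
#' planted clusters per the mixing proportions.  Binary symptom items are
#' drawn independently given the cluster from its Bernoulli profile
#' (optionally correlated through a shared latent severity factor).
#' Background covariates are drawn independently of cluster from the
#' configured marginals.  The emitted table is complete; apply
#' [inject_missingness()] to add survey missingness.
#'
#' @param config A [generator_config()].
#' @return List with elements `table` (a [cohort_table()]) and `truth`
#'   (data frame `subject_id`, `cluster` with 0 = asymptomatic, plus the
#'   true cluster log-HR matrix as attribute `cluster_loghr`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_clusters
  subject_id <- sprintf("S%06d", seq_len(n))

  cluster <- ifelse(
    stats::runif(n) < config$asymptomatic_fraction, 0L,
    sample.int(k, n, replace = TRUE, prob = config$mixing)
  )

  items <- colnames(config$symptom_profiles)
  sym <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  sympt <- which(cluster > 0L)
  if (length(sympt)) {
    probs <- config$symptom_profiles[cluster[sympt], , drop = FALSE]
    if (config$severity_correlation != 0) {
      z <- stats::rnorm(length(sympt))
      probs <- stats::plogis(stats::qlogis(pmin(pmax(probs, 1e-6), 1 - 1e-6)) +
                               config$severity_correlation * z)
    }
    sym[sympt, ] <- matrix(
      as.integer(stats::runif(length(probs)) < probs),
      nrow = length(sympt)
    )
  }

  cm <- config$covariate_model
  age <- pmin(pmax(stats::rnorm(n, cm$age$mean, cm$age$sd), cm$age$min), cm$age$max)
  covars <- data.frame(
    age = round(age, 1),
    bmi = round(pmax(stats::rnorm(n, cm$bmi$mean, cm$bmi$sd), 14), 1),
    sex = sample(c("female", "male"), n, TRUE,
                 prob = c(cm$p_female, 1 - cm$p_female)),
    smoking = sample(names(cm$smoking), n, TRUE, prob = cm$smoking),
    cohort = sample(names(cm$cohort), n, TRUE, prob = cm$cohort),
    occupational_exposure = as.integer(stats::runif(n) < cm$p_occupational_exposure),
    education = sample(names(cm$education), n, TRUE, prob = cm$education),
    ses = sample(names(cm$ses), n, TRUE, prob = cm$ses),
    stringsAsFactors = FALSE
  )

  data <- cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE),
                as.data.frame(sym), covars)
  table <- cohort_table(data, default_schema(config))
  truth <- data.frame(subject_id = subject_id, cluster = cluster,
                      stringsAsFactors = FALSE)
  attr(truth, "cluster_loghr") <- config$survival_model$cluster_loghr
  list(table = table, truth = truth)
}

#' Simulate competing-risks survival outcomes
#'
#' Latent cause-specific exponential event times are drawn per subject
#' (one per cause) with hazard `baseline_hazard[cause] * exp(lp)`, where
#' the linear predictor combines the subject's true cluster log-HR for
#' that cause and the covariate log-HRs.  Observed time is the minimum of
#' the latent times and the administrative end of follow-up; subjects
#' reaching the administrative end are censored.  Deaths carry an
#' underlying-cause ICD-10 code drawn from the cause's code block.
#'
#' @param truth Truth-label data frame from [generate_cohort()].
#' @param covariates Data frame with `age`, `sex`, `smoking` per subject
#'   (same order as `truth`).
#' @param survival_model See [default_survival_model()].
#' @param seed Integer seed.
#' @return Data frame `subject_id`, `time` (years), `event` (0/1),
#'   `cause` (NA for censored), `icd10` (underlying cause code, NA for
#'   censored).
#' @export
generate_survival <- function(truth, covariates, survival_model, seed = 1L) {
  if (any(unlist(survival_model$baseline_hazards) <= 0)) {
    stop("baseline hazards must be positive")
  }
  stopifnot(nrow(truth) == nrow(covariates))
  set.seed(seed)
  n <- nrow(truth)
  causes <- names(survival_model$baseline_hazards)
  cv <- survival_model$covariate_loghr
  lp_cov <- cv$age * (covariates$age - survival_model$age_center) +
    cv$male * (covariates$sex == "male") +
    cv$smoking_current * (covariates$smoking == "current") +
    cv$smoking_former * (covariates$smoking == "former")

  times <- matrix(NA_real_, n, length(causes), dimnames = list(NULL, causes))
  for (cz in causes) {
    lp_cl <- ifelse(truth$cluster > 0L,
                    survival_model$cluster_loghr[pmax(truth$cluster, 1L), cz], 0)
    rate <- survival_model$baseline_hazards[[cz]] * exp(lp_cov + lp_cl)
    times[, cz] <- stats::rexp(n, rate = rate)
  }
  tmin <- apply(times, 1L, min)
  admin <- survival_model$admin_end
  event <- as.integer(tmin < admin)
  cause <- rep(NA_character_, n)
  cause[event == 1L] <- causes[apply(times[event == 1L, , drop = FALSE], 1L,
                                     which.min)]
  icd_pool <- list(
    cardiovascular = c("I21", "I25", "I50", "I63", "I64", "I70"),
    respiratory = c("J44", "J45", "J18", "J84", "J96"),
    lung_cancer = c("C34", "C33"),
    other = c("A41", "G30", "K72", "N18", "E11", "C18", "C50", "C61", "X70")
  )
  icd10 <- rep(NA_character_, n)
  for (cz in causes) {
    idx <- which(!is.na(cause) & cause == cz)
    if (length(idx)) icd10[idx] <- sample(icd_pool[[cz]], length(idx), TRUE)
  }
  data.frame(subject_id = truth$subject_id,
             time = pmin(tmin, admin), event = event,
             cause = cause, icd10 = icd10, stringsAsFactors = FALSE)
}

#' Inject survey missingness into a cohort table
#'
#' Blanks survey-role cells only; register and outcome data are never
#' touched.  Under MCAR every eligible cell is blanked independently with
#' probability `rate`.  Under MAR the per-cell probability depends on the
#' subject's cohort (per-cohort base rates) and age (logit-linear in
#' standardised age), and the conditioning variables themselves (`cohort`,
#' `age`) stay observed so the mechanism remains missing-at-random.
#'
#' @param table A [cohort_table()].
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Base missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param vars Variables to blank; default all survey variables
#'   (minus `cohort`/`age` under MAR).  Register variables are refused.
#' @param cohort_rates Named per-cohort base rates (MAR only); default
#'   `rate` for every cohort.
#' @param age_slope Logit-scale slope on standardised age (MAR only).
#' @return A `cohort_table` with missing survey cells.
#' @export
inject_missingness <- function(table, mechanism = c("MCAR", "MAR"), rate,
                               seed = 1L, vars = NULL,
                               cohort_rates = NULL, age_slope = 0.5) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  schema <- table$schema
  sv <- survey_vars(schema)
  if (is.null(vars)) {
    vars <- if (mechanism == "MAR") setdiff(sv, c("cohort", "age")) else sv
  }
  bad <- setdiff(vars, sv)
  if (length(bad)) {
    stop("refusing to blank non-survey variable(s): ", paste(bad, collapse = ", "))
  }
  if (rate == 0) return(table)
  set.seed(seed)
  data <- table$data
  n <- nrow(data)
  if (mechanism == "MCAR") {
    p <- rep(rate, n)
  } else {
    if (!all(c("cohort", "age") %in% names(data))) {
      stop("MAR mechanism needs cohort and age columns")
    }
    if (is.null(cohort_rates)) {
      lv <- schema_levels(schema, "cohort")
      cohort_rates <- stats::setNames(rep(rate, length(lv)), lv)
    }
    base <- cohort_rates[data$cohort]
    zage <- as.numeric(scale(data$age))
    p <- stats::plogis(stats::qlogis(pmin(pmax(base, 1e-6), 1 - 1e-6)) +
                         age_slope * zage)
  }
  for (v in vars) {
    hit <- stats::runif(n) < p
    data[[v]][hit] <- NA
  }
  out <- table
  out$data <- data
  out
}

#' Generate ICD-10 specialist-care histories
#'
#' Per subject, a Poisson number of comorbidity-relevant contacts (codes
#' drawn from the Charlson category prefixes) and a Poisson number of
#' other specialist contacts (codes outside the map), dated uniformly in
#' the configured lookback window ending in the survey year.  Calibrated
#' so that with the default `cci_rate` about 93 percent of subjects have
#' no comorbidity-index-relevant codes.
#'
#' @param config A [generator_config()] (uses `comorbidity_model`).
#' @param subjects Data frame with `subject_id`.
#' @param index_year Survey (index) year; dates fall in
#'   `[index_year - lookback_years, index_year]`.
#' @param seed Integer seed.
#' @return Data frame `subject_id`, `icd10`, `date` (class `Date`).
#' @export
generate_icd_histories <- function(config, subjects, index_year = 2008,
                                   seed = 1L) {
  cmod <- config$comorbidity_model
  set.seed(seed)
  map <- default_cci_map()
  cci_codes <- unlist(lapply(map$categories, `[[`, "prefixes"), use.names = FALSE)
  other_codes <- c("H25", "H40", "K35", "K40", "M17", "M23", "M54", "N20",
                   "O80", "R07", "R10", "S52", "S82", "Z03")
  lo <- as.Date(sprintf("%d-01-01", index_year - cmod$lookback_years))
  hi <- as.Date(sprintf("%d-12-31", index_year))
  span <- as.integer(hi - lo)

  draw <- function(ids, rate, pool) {
    n_ev <- stats::rpois(length(ids), rate)
    tot <- sum(n_ev)
    if (tot == 0L) {
      return(data.frame(subject_id = character(0), icd10 = character(0),
                        date = as.Date(character(0)), stringsAsFactors = FALSE))
    }
    data.frame(
      subject_id = rep(ids, n_ev),
      icd10 = sample(pool, tot, TRUE),
      date = lo + sample.int(span + 1L, tot, TRUE) - 1L,
      stringsAsFactors = FALSE
    )
  }
  rec <- rbind(draw(subjects$subject_id, cmod$cci_rate, cci_codes),
               draw(subjects$subject_id, cmod$other_rate, other_codes))
  rec <- rec[order(rec$subject_id, rec$date), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
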
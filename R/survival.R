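#' Default cause-of-death ICD-10 blocks
#'
#' Underlying-cause prefixes mapped to the three named cause-specific
#' outcomes: circulatory codes (I00-I99) to cardiovascular, respiratory
#' codes (J00-J99) to respiratory, and C33-C34 to lung cancer.  Lung
#' cancer is matched before any broader block; anything unmatched is
#' "other".  The blocks are configuration, not baked in.
#'
#' @return Named list of prefix vectors, in match order.
#' @export
default_cause_map <- function() {
  list(lung_cancer = c("C33", "C34"),
       cardiovascular = "I",
       respiratory = "J")
}

#' Assemble survival records from death data
#'
#' Subjects without a death record are treated as having survived to the
#' administrative end of follow-up and are censored there.  Deaths are
#' assigned a cause by ICD-10 prefix via `cause_map` ("other" when no
#' block matches).  Cohorts whose register follow-up is shorter than
#' `min_followup` are excluded entirely (with a recorded count), matching
#' the handling of a cohort with only one year of register coverage.
#'
#' @param subjects Data frame `subject_id` (+ `cohort` if cohort
#'   exclusions apply).
#' @param deaths Data frame `subject_id`, `time` (years since baseline),
#'   `icd10` (underlying cause).
#' @param followup_end Administrative end of follow-up in years.
#' @param cause_map See [default_cause_map()].
#' @param cohort_followup Optional named vector: register follow-up years
#'   per cohort.
#' @param min_followup Minimum register follow-up for inclusion (years).
#' @return Data frame `subject_id`, `time`, `event`, `cause`; excluded
#'   subject count in attribute `"n_excluded"`.
#' @export
build_survival_records <- function(subjects, deaths, followup_end,
                                   cause_map = default_cause_map(),
                                   cohort_followup = NULL,
                                   min_followup = 0) {
  n_excluded <- 0L
  if (!is.null(cohort_followup) && min_followup > 0) {
    short <- names(cohort_followup)[cohort_followup < min_followup]
    if (length(short)) {
      drop <- subjects$cohort %in% short
      n_excluded <- sum(drop)
      message("excluding ", n_excluded, " subject(s) from cohort(s) with <",
              min_followup, "y register follow-up: ",
              paste(short, collapse = ", "))
      subjects <- subjects[!drop, , drop = FALSE]
    }
  }
  if (any(deaths$time < 0)) {
    stop("death before baseline for subject(s): ",
         paste(utils::head(deaths$subject_id[deaths$time < 0], 5), collapse = ", "))
  }
  m <- match(subjects$subject_id, deaths$subject_id)
  time <- ifelse(is.na(m), followup_end, pmin(deaths$time[m], followup_end))
  event <- as.integer(!is.na(m) & deaths$time[m] <= followup_end)
  cause <- rep(NA_character_, nrow(subjects))
  dead <- which(event == 1L)
  if (length(dead)) {
    codes <- deaths$icd10[m[dead]]
    cz <- rep("other", length(codes))
    for (nm in rev(names(cause_map))) { # earlier blocks take precedence
      hit <- vapply(codes, function(cd) any(startsWith(cd, cause_map[[nm]])),
                    logical(1))
      cz[hit] <- nm
    }
    cause[dead] <- cz
  }
  out <- data.frame(subject_id = subjects$subject_id, time = time,
                    event = event, cause = cause, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates via [survival::survfit()], returned tidy with
#' the numbers at risk at 0, 5, 10, 15 and 20 years.
#'
#' @param records Data frame `time`, `event`.
#' @param group_labels Group per subject (e.g. cluster / asymptomatic).
#' @param at_risk_times Times for the at-risk table.
#' @return List with `curve` (group, time, surv, lower, upper) and
#'   `at_risk` (group x time counts).
#' @export
km_curve <- function(records, group_labels,
                     at_risk_times = c(0, 5, 10, 15, 20)) {
  stopifnot(nrow(records) == length(group_labels))
  grp <- if (is.factor(group_labels)) group_labels else factor(group_labels)
  empty <- levels(grp)[table(grp) == 0L]
  if (length(empty)) {
    warning("skipping empty group(s): ", paste(empty, collapse = ", "))
    grp <- droplevels(grp)
  }
  df <- data.frame(time = records$time, event = records$event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curve <- data.frame(group = strata, time = sm$time, surv = sm$surv,
                      lower = sm$lower, upper = sm$upper,
                      stringsAsFactors = FALSE)
  ar <- summary(fit, times = at_risk_times, extend = TRUE)
  ar_strata <- if (is.null(ar$strata)) rep(levels(grp)[1], length(ar$time)) else
    sub("^group=", "", as.character(ar$strata))
  at_risk <- stats::xtabs(n.risk ~ group + time,
                          data = data.frame(group = ar_strata, time = ar$time,
                                            n.risk = ar$n.risk))
  list(curve = curve, at_risk = at_risk)
}

#' Events-per-covariate guard
#'
#' An analysis is fitted only when it has at least 10 events per
#' estimated covariate; anything below is skipped and flagged, never
#' silently fitted.
#'
#' @param n_events Number of (target) events.
#' @param n_covariates Number of estimated model parameters.
#' @return `TRUE` iff `n_events >= 10 * n_covariates`.
#' @export
epv_guard <- function(n_events, n_covariates) {
  stopifnot(n_events >= 0, n_covariates >= 0)
  n_events >= 10 * n_covariates
}

# number of coefficients a factor/numeric covariate contributes
n_params <- function(data, vars) {
  sum(vapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) 1L else max(length(unique(x[!is.na(x)])) - 1L, 1L)
  }, integer(1)))
}

#' Cox proportional hazards fit for cluster exposure
#'
#' Fits `Surv(time, event) ~ exposure + confounders` with the Efron tie
#' convention, the exposure being the cluster label with the asymptomatic
#' group as reference.  The fitting engine is [survival::coxph()]; the
#' contract is the per-cluster log-HR and variance output.
#'
#' @param data Data frame with `time`, `event`, the exposure column and
#'   confounders.
#' @param exposure Name of the exposure factor; its first level is the
#'   reference.
#' @param confounders Character vector of confounder columns (empty =
#'   crude model).
#' @return A `model_fit`: `coef`, `var` (diagonal), `vcov`, `n_events`,
#'   `converged`, `exposure_terms`, and the underlying `coxph` object in
#'   `engine`.
#' @export
fit_cox <- function(data, exposure = "group", confounders = character()) {
  data[[exposure]] <- droplevels(as.factor(data[[exposure]]))
  rhs <- paste(c(exposure, confounders), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = data, ties = "efron"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    }
  )
  coefs <- stats::coef(fit)
  vc <- stats::vcov(fit)
  ex <- grep(paste0("^", exposure), names(coefs), value = TRUE)
  structure(list(
    coef = coefs, var = diag(vc), vcov = vc,
    n_events = sum(data$event),
    converged = fit_usable(coefs, diag(vc), ex),
    warning = attr(fit, "fit_warning"),
    exposure_terms = ex, engine = fit
  ), class = "model_fit")
}

# a fit is usable for pooling when every coefficient is finite and the
# exposure terms are bounded away from a monotone-likelihood blow-up;
# a drifting confounder (rare level, no events) is recorded as a warning
# but does not discard the exposure estimates
fit_usable <- function(coefs, vars, exposure_terms, bound = 15) {
  all(is.finite(coefs)) && all(is.finite(vars)) &&
    all(abs(coefs[exposure_terms]) < bound) &&
    all(sqrt(vars[exposure_terms]) < bound)
}

#' Fine-Gray subdistribution hazards fit
#'
#' Regression on the subdistribution hazard of one cause: subjects who
#' die of competing causes remain in the risk set through censoring
#' weights.  Implemented by expanding the data with
#' [survival::finegray()] and fitting a weighted Cox model.  With zero
#' competing events the fit coincides with the cause-specific Cox model.
#'
#' @param data Data frame with `time`, `event`, `cause`, the exposure
#'   column and confounders.
#' @param cause Target cause (a value of `data$cause`).
#' @param exposure,confounders As in [fit_cox()].
#' @return A `model_fit`; `n_events` counts target-cause events.
#' @export
fit_fine_gray <- function(data, cause, exposure = "group",
                          confounders = character()) {
  target_events <- sum(data$event == 1L & data$cause %in% cause)
  if (target_events == 0L) stop("no events of cause '", cause, "'")
  data[[exposure]] <- droplevels(as.factor(data[[exposure]]))
  causes <- unique(data$cause[data$event == 1L])
  status <- factor(ifelse(data$event == 0L, "censor", data$cause),
                   levels = c("censor", causes))
  fgdat <- survival::finegray(
    survival::Surv(time, status) ~ ., data = cbind(data, status = status),
    etype = cause
  )
  rhs <- paste(c(exposure, confounders), collapse = " + ")
  fml <- stats::as.formula(
    paste("survival::Surv(fgstart, fgstop, fgstatus) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = fgdat, weights = fgdat$fgwt, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(fml, data = fgdat, weights = fgdat$fgwt, ties = "efron"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    }
  )
  coefs <- stats::coef(fit)
  vc <- stats::vcov(fit)
  ex <- grep(paste0("^", exposure), names(coefs), value = TRUE)
  structure(list(
    coef = coefs, var = diag(vc), vcov = vc,
    n_events = target_events,
    converged = fit_usable(coefs, diag(vc), ex),
    warning = attr(fit, "fit_warning"),
    exposure_terms = ex, engine = fit
  ), class = "model_fit")
}

#' Non-parametric cumulative incidence functions
#'
#' Aalen-Johansen estimates of the cumulative incidence of each cause in
#' the presence of the others; the cause-specific curves sum to at most
#' one at every time.
#'
#' @param data Data frame with `time`, `event`, `cause`.
#' @return Data frame `time`, one column per cause.
#' @export
cif_estimate <- function(data) {
  causes <- unique(data$cause[data$event == 1L])
  status <- factor(ifelse(data$event == 0L, "censor", data$cause),
                   levels = c("censor", causes))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           data = cbind(data, status = status))
  ps <- fit$pstate
  colnames(ps) <- fit$states
  out <- data.frame(time = fit$time)
  for (cz in causes) out[[cz]] <- ps[, cz]
  out
}

#' Proportional hazards check via scaled Schoenfeld residuals
#'
#' Per-covariate zero-slope score test of the scaled Schoenfeld
#' residuals against time ([survival::cox.zph()]), plus the residual
#' series for visual inspection.
#'
#' @param fit A `model_fit` from [fit_cox()].
#' @param transform Time transform for the test (default `"km"`).
#' @return List with `table` (term, chisq, df, p) and `residuals`
#'   (time x term matrix of scaled residuals).
#' @export
check_proportionality <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "model_fit"))
  zp <- survival::cox.zph(fit$engine, transform = transform)
  tab <- as.data.frame(zp$table)
  tab$term <- rownames(zp$table)
  rownames(tab) <- NULL
  list(table = tab[, c("term", "chisq", "df", "p")],
       residuals = data.frame(time = zp$time, zp$y, check.names = FALSE))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance
#' T = W + (1 + 1/m) B with W the mean within-imputation variance and B
#' the between-imputation sample variance.  The confidence interval uses
#' a t reference with Barnard-Rubin small-sample degrees of freedom
#' (reducing to the classical Rubin df when the complete-data df is
#' taken as infinite).  Pooling happens on the log-HR scale;
#' exponentiation to the HR scale is reporting only.
#'
#' @param estimates Per-imputation estimates (log-HRs).
#' @param variances Matching per-imputation variances.
#' @param conf_level Confidence level (default 0.95).
#' @param df_com Complete-data degrees of freedom (default `Inf`).
#' @return A `pooled_estimate`: `estimate`, `W`, `B`, `T`, `df`,
#'   `ci_low`, `ci_high` (log scale), and `hr`, `hr_low`, `hr_high`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95,
                       df_com = Inf) {
  m <- length(estimates)
  if (m == 0L) stop("no estimates to pool")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1L) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B > 0 && m > 1L) {
    r <- (1 + 1 / m) * B / W
    df_old <- (m - 1) * (1 + 1 / r)^2
    lambda <- (1 + 1 / m) * B / Tv
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else {
      df_old
    }
  } else {
    df <- Inf
  }
  tcrit <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- qbar - tcrit * sqrt(Tv)
  hi <- qbar + tcrit * sqrt(Tv)
  structure(list(estimate = qbar, W = W, B = B, T = Tv, df = df, m = m,
                 ci_low = lo, ci_high = hi,
                 hr = exp(qbar), hr_low = exp(lo), hr_high = exp(hi)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (%.3f-%.3f), log-HR %.4f, T %.5f, df %s, m %d\n",
              x$hr, x$hr_low, x$hr_high, x$estimate, x$T,
              ifelse(is.finite(x$df), sprintf("%.1f", x$df), "Inf"), x$m))
  invisible(x)
}

default_strata <- function() {
  c("overall", "sex", "age", "cci", "asthma", "copd",
    "followup5", "followup10")
}

stratum_subsets <- function(data, stratum) {
  switch(stratum,
    overall = list(overall = data),
    sex = split(data, data$sex),
    age = list(`age<=60` = data[data$age <= 60, ],
               `age>60` = data[data$age > 60, ]),
    cci = split(data, paste0("cci", data$cci_cat)),
    asthma = list(asthma_yes = data[data$asthma, ],
                  asthma_no = data[!data$asthma, ]),
    copd = list(copd_yes = data[data$copd, ],
                copd_no = data[!data$copd, ]),
    followup5 = list(`followup<=5` = truncate_followup(data, 5)),
    followup10 = list(`followup<=10` = truncate_followup(data, 10)),
    stop("unknown stratum: ", stratum)
  )
}

truncate_followup <- function(data, horizon) {
  over <- data$time > horizon
  data$event[over] <- 0L
  data$cause[over] <- NA_character_
  data$time[over] <- horizon
  data
}

#' Run the pooled mortality analysis
#'
#' For every outcome (all-cause via Cox; cardiovascular, respiratory and
#' lung-cancer mortality via Fine-Gray), adjustment level (crude,
#' adjusted) and stratum, the model is fitted once per imputed dataset
#' using that imputation's cluster labels, with the asymptomatic group
#' as reference, and the per-cluster log-HRs are pooled with Rubin's
#' rules.  Any analysis failing the 10-events-per-covariate guard is
#' skipped and logged, never fitted; follow-up strata administratively
#' censor at their horizon.  Within a stratum defined by a confounder
#' (sex, CCI, asthma, COPD) that confounder is dropped from the adjusted
#' model.
#'
#' @param analysis_data List of per-imputation data frames, each with
#'   `time`, `event`, `cause`, `group` (factor, reference level first)
#'   and the confounder columns.
#' @param confounders Confounders for the adjusted models.
#' @param outcomes Outcomes to run (default all four).
#' @param strata Strata to run (see `default_strata()`; default
#'   `"overall"`).
#' @param adjustments `"crude"`, `"adjusted"` or both.
#' @return List with `results` (tidy data frame: outcome, adjustment,
#'   stratum, cluster, hr, ci_low, ci_high, n_events, m) and `skipped`
#'   (data frame of skipped analyses with reasons).
#' @export
run_mortality_analysis <- function(analysis_data,
                                   confounders = c("age", "bmi", "sex",
                                                   "smoking", "cohort",
                                                   "occupational_exposure",
                                                   "education", "ses",
                                                   "cci_cat", "asthma", "copd"),
                                   outcomes = c("all_cause", "cardiovascular",
                                                "respiratory", "lung_cancer"),
                                   strata = "overall",
                                   adjustments = c("crude", "adjusted")) {
  results <- list()
  skipped <- list()
  m <- length(analysis_data)
  stratum_conf_drop <- list(sex = "sex", cci = "cci_cat",
                            asthma = "asthma", copd = "copd")
  for (outcome in outcomes) {
    for (stratum in strata) {
      sub_names <- names(stratum_subsets(analysis_data[[1L]], stratum))
      for (sn in sub_names) {
        for (adj in adjustments) {
          conf <- if (adj == "adjusted") {
            setdiff(confounders, stratum_conf_drop[[stratum]])
          } else {
            character()
          }
          fits <- vector("list", m)
          skip_reason <- NULL
          for (i in seq_len(m)) {
            d <- stratum_subsets(analysis_data[[i]], stratum)[[sn]]
            d$group <- droplevels(as.factor(d$group))
            n_ev <- if (outcome == "all_cause") sum(d$event == 1L) else
              sum(d$event == 1L & d$cause %in% outcome)
            # estimated parameters: exposure dummies + confounder terms
            p <- n_params(d, conf) + (nlevels(d$group) - 1L)
            if (!epv_guard(n_ev, p)) {
              skip_reason <- sprintf("%d events < 10 x %d covariates", n_ev, p)
              break
            }
            fits[[i]] <- tryCatch({
              if (outcome == "all_cause") {
                fit_cox(d, "group", conf)
              } else {
                fit_fine_gray(d, outcome, "group", conf)
              }
            }, error = function(e) conditionMessage(e))
          }
          if (!is.null(skip_reason) ||
              any(vapply(fits, is.character, logical(1)))) {
            if (is.null(skip_reason)) {
              skip_reason <- fits[[which(vapply(fits, is.character,
                                                logical(1)))[1L]]]
            }
            skipped[[length(skipped) + 1L]] <- data.frame(
              outcome = outcome, adjustment = adj, stratum = sn,
              reason = skip_reason, stringsAsFactors = FALSE)
            next
          }
          ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
          if (!all(ok)) {
            warning(sum(!ok), " non-converged fit(s) excluded from pooling (",
                    outcome, ", ", adj, ", ", sn, ")")
            fits <- fits[ok]
          }
          if (!length(fits)) {
            skipped[[length(skipped) + 1L]] <- data.frame(
              outcome = outcome, adjustment = adj, stratum = sn,
              reason = "no converged fits", stringsAsFactors = FALSE)
            next
          }
          terms <- fits[[1L]]$exposure_terms
          for (term in terms) {
            est <- vapply(fits, function(f) f$coef[[term]], numeric(1))
            vv <- vapply(fits, function(f) f$var[[term]], numeric(1))
            pe <- rubin_pool(est, vv)
            results[[length(results) + 1L]] <- data.frame(
              outcome = outcome, adjustment = adj, stratum = sn,
              cluster = sub("^group", "", term),
              hr = pe$hr, ci_low = pe$hr_low, ci_high = pe$hr_high,
              log_hr = pe$estimate, se = sqrt(pe$T),
              n_events = mean(vapply(fits, `[[`, numeric(1), "n_events")),
              m = length(fits), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(
    results = if (length(results)) do.call(rbind, results) else
      data.frame(),
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(outcome = character(), adjustment = character(),
                 stratum = character(), reason = character())
  )
}
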
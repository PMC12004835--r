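#' Pipeline configuration
#'
#' One structure driving simulate -> impute -> cluster -> consensus ->
#' comorbidity -> survival -> characterisation.  The `test` profile keeps
#' problem sizes small enough for interactive runs; the `paper_scale`
#' profile uses 100 imputations and the full 2-10 cluster scan.
#'
#' @param profile `"test"` or `"paper_scale"`.
#' @param seed Global integer seed; every stage derives its stream from it.
#' @param n_subjects,m,k,k_range,mice_iterations,n_bits Stage knobs
#'   overriding the profile defaults.
#' @param scan Run the cluster-count scan (otherwise fit `k` directly).
#' @param strata Strata for the mortality analysis.
#' @param index_year Survey year anchoring registers.
#' @param generator Optional pre-built [generator_config()] override.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("test", "paper_scale"), seed = 1L,
                            n_subjects = NULL, m = NULL, k = 5L,
                            k_range = NULL, mice_iterations = NULL,
                            n_bits = 6L, scan = FALSE,
                            strata = "overall", index_year = 2008L,
                            generator = NULL) {
  profile <- match.arg(profile)
  defaults <- if (profile == "test") {
    list(n_subjects = 2000L, m = 3L, k_range = 2:10, mice_iterations = 3L)
  } else {
    list(n_subjects = 63060L, m = 100L, k_range = 2:10, mice_iterations = 10L)
  }
  cfg <- list(
    profile = profile, seed = as.integer(seed),
    n_subjects = if (is.null(n_subjects)) defaults$n_subjects else as.integer(n_subjects),
    m = if (is.null(m)) defaults$m else as.integer(m),
    k = as.integer(k),
    k_range = if (is.null(k_range)) defaults$k_range else k_range,
    mice_iterations = if (is.null(mice_iterations)) defaults$mice_iterations
      else as.integer(mice_iterations),
    n_bits = as.integer(n_bits), scan = scan,
    strata = strata, index_year = as.integer(index_year),
    generator = generator
  )
  if (cfg$m < 1L || cfg$k < 1L || cfg$n_subjects < 10L) {
    stop("invalid pipeline configuration")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, injects survey missingness, imputes m
#' completed datasets, clusters the symptomatic subjects of each
#' imputation, aligns and majority-votes the labels, computes the
#' modified comorbidity index from generated ICD-10 histories, runs the
#' pooled mortality analysis against the asymptomatic reference, and
#' writes every artifact (plus a run log of seeds, counts and skips)
#' under `out_dir`.  Deterministic given `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created).
#' @return Invisibly, a list of the in-memory artifacts.
#' @export
run_pipeline <- function(config, out_dir = tempfile("respclust_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  seed <- config$seed
  say("pipeline start: profile=", config$profile, " seed=", seed,
      " n=", config$n_subjects, " m=", config$m)

  # --- simulate ---------------------------------------------------------
  gcfg <- config$generator
  if (is.null(gcfg)) {
    gcfg <- generator_config(n_subjects = config$n_subjects, seed = seed)
  }
  gen <- generate_cohort(gcfg)
  truth <- gen$truth
  complete_table <- gen$table
  surv_raw <- generate_survival(truth, complete_table$data,
                                gcfg$survival_model, seed = seed + 1L)
  histories <- generate_icd_histories(gcfg, truth,
                                      index_year = config$index_year,
                                      seed = seed + 2L)
  missing_table <- inject_missingness(complete_table,
                                      mechanism = gcfg$missingness$mechanism,
                                      rate = gcfg$missingness$rate,
                                      seed = seed + 3L)
  write_cohort(missing_table, file.path(out_dir, "cohort.csv"))
  write_schema(missing_table$schema, file.path(out_dir, "schema.csv"))
  utils::write.csv(truth, file.path(out_dir, "truth_labels.csv"),
                   row.names = FALSE)
  say("simulated ", n_subjects(complete_table), " subjects; ",
      sum(truth$cluster == 0L), " asymptomatic by truth; ",
      sum(surv_raw$event), " deaths; ",
      nrow(histories), " ICD-10 records")

  # --- impute -----------------------------------------------------------
  iset <- mice_rf(missing_table, m = config$m,
                  iterations = config$mice_iterations, seed = seed + 4L)
  write_imputation_set(iset, file.path(out_dir, "imputations"))
  say("imputed m=", iset$m, " datasets (", config$mice_iterations,
      " sweeps each)")

  # --- cluster each imputation -----------------------------------------
  n <- n_subjects(complete_table)
  ids <- complete_table$data$subject_id
  per_imp_labels <- matrix(0L, n, iset$m,
                           dimnames = list(ids, NULL))
  suggested_k <- NA_integer_
  for (i in seq_len(iset$m)) {
    split_i <- eligibility_split(iset$tables[[i]])
    sympt <- split_i$symptomatic
    if (i == 1L && config$scan) {
      sc <- scan_k(sympt, k_range = config$k_range, n_bits = config$n_bits,
                   seed = seed + 5L)
      suggested_k <- sc$suggested_k
      utils::write.csv(sc$metrics, file.path(out_dir, "scan_k.csv"),
                       row.names = FALSE)
      say("cluster-count scan over ", min(config$k_range), "-",
          max(config$k_range), ": suggested k=", suggested_k,
          " (fitting k=", config$k, ")")
    }
    fit <- lshkp_fit(sympt, k = config$k, n_bits = config$n_bits,
                     seed = seed + 5L + i)
    per_imp_labels[sympt$data$subject_id, i] <- unname(fit$labels)
    say("imputation ", i, ": clustered ", n_subjects(sympt),
        " symptomatic subjects, objective ",
        format(fit$objective, digits = 8), ", ", fit$n_iter, " iterations")
  }

  # --- consensus --------------------------------------------------------
  # subjects symptomatic in every imputation get an aligned majority-vote
  # label; the rest are asymptomatic (0) wherever the vote says so
  always_sympt <- rowSums(per_imp_labels > 0L) == iset$m
  cons_labels <- integer(n)
  agreement <- rep(1, n)
  if (any(always_sympt)) {
    mv <- majority_vote(per_imp_labels[always_sympt, , drop = FALSE],
                        k = config$k)
    cons_labels[always_sympt] <- mv$labels
    agreement[always_sympt] <- mv$agreement
    # map the per-imputation label columns through the same alignment for
    # downstream use
    per_imp_labels[always_sympt, ] <- mv$aligned
  }
  consensus <- data.frame(subject_id = ids, consensus = cons_labels,
                          agreement = agreement, stringsAsFactors = FALSE)
  utils::write.csv(consensus, file.path(out_dir, "consensus_labels.csv"),
                   row.names = FALSE)
  say("consensus: ", sum(cons_labels > 0L), " symptomatic subjects, mean ",
      "agreement ", format(mean(agreement[always_sympt]), digits = 4))

  # --- comorbidity ------------------------------------------------------
  cci <- cci_scores(histories, ids, index_year = config$index_year)
  flags <- flag_asthma_copd(histories, NULL, index_year = config$index_year,
                            subject_ids = ids)
  comorbidity <- data.frame(subject_id = ids, cci = unname(cci),
                            cci_cat = cci_category(unname(cci)),
                            asthma = flags$asthma, copd = flags$copd,
                            stringsAsFactors = FALSE)
  utils::write.csv(comorbidity, file.path(out_dir, "comorbidity.csv"),
                   row.names = FALSE)
  say("comorbidity: ", round(100 * mean(cci == 0), 1), "% with modified CCI 0")

  # --- survival ---------------------------------------------------------
  deaths <- surv_raw[surv_raw$event == 1L,
                     c("subject_id", "time", "icd10")]
  records <- build_survival_records(
    data.frame(subject_id = ids, cohort = complete_table$data$cohort,
               stringsAsFactors = FALSE),
    deaths, followup_end = gcfg$survival_model$admin_end)
  # confounders come from each imputation's completed table, so the
  # per-imputation models see imputation-consistent covariates
  analysis_data <- lapply(seq_len(iset$m), function(i) {
    d <- cbind(records,
               iset$tables[[i]]$data[match(records$subject_id, ids),
                                     c("age", "bmi", "sex", "smoking", "cohort",
                                       "occupational_exposure", "education",
                                       "ses")],
               comorbidity[match(records$subject_id, ids),
                           c("cci_cat", "asthma", "copd")])
    lab <- per_imp_labels[records$subject_id, i]
    d$group <- factor(ifelse(lab == 0L, "asymptomatic",
                             paste0("cluster", lab)),
                      levels = c("asymptomatic",
                                 paste0("cluster", seq_len(config$k))))
    d
  })
  mort <- run_mortality_analysis(analysis_data, strata = config$strata)
  utils::write.csv(mort$results, file.path(out_dir, "mortality_results.csv"),
                   row.names = FALSE)
  utils::write.csv(mort$skipped, file.path(out_dir, "mortality_skipped.csv"),
                   row.names = FALSE)
  say("mortality analysis: ", nrow(mort$results), " pooled estimates, ",
      nrow(mort$skipped), " skipped analyses, ", sum(records$event),
      " deaths in analysis set")

  km <- km_curve(records, analysis_data[[1L]]$group)
  utils::write.csv(km$curve, file.path(out_dir, "km_curve.csv"),
                   row.names = FALSE)

  # --- characterisation -------------------------------------------------
  pooled <- pool_descriptive(iset)
  char <- characterize_clusters(consensus$consensus, pooled)
  utils::write.csv(char, file.path(out_dir, "cluster_characterization.csv"),
                   row.names = FALSE)
  histo <- symptom_count_distribution(iset)
  utils::write.csv(histo, file.path(out_dir, "symptom_count_distribution.csv"),
                   row.names = FALSE)

  say("pipeline done")
  writeLines(c(paste0("respclust ",
                      as.character(utils::packageVersion("respclust")),
                      " | R ", R.version.string),
               log_lines),
             file.path(out_dir, "run_log.txt"))
  invisible(list(
    config = config, out_dir = out_dir, truth = truth,
    table = missing_table, imputations = iset,
    per_imputation_labels = per_imp_labels, consensus = consensus,
    comorbidity = comorbidity, records = records,
    mortality = mort, characterization = char,
    symptom_distribution = histo, suggested_k = suggested_k
  ))
}

p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Characterise clusters against all other clusters
#'
#' Per cluster and variable: the within-cluster proportion (categorical;
#' for binary/ordinal the proportion above the lowest level) or mean
#' (continuous), with a p-value comparing the cluster to all other
#' clusters pooled — Pearson chi-square for categorical variables,
#' Mann-Whitney U for continuous — and star notation at the
#' 0.05/0.01/0.001/0.0001 thresholds.  P-values are unadjusted;
#' `bonferroni = TRUE` adds an adjusted column.
#'
#' @param consensus_labels Integer labels (0 = asymptomatic is excluded
#'   from the comparison).
#' @param pooled_table Descriptively pooled [cohort_table()].
#' @param vars Variables to characterise; default all schema variables.
#' @param bonferroni Add a Bonferroni-adjusted p column (off by default).
#' @return Data frame `variable`, `cluster`, `n`, `summary`, `p_value`,
#'   `stars`.
#' @export
characterize_clusters <- function(consensus_labels, pooled_table,
                                  vars = NULL, bonferroni = FALSE) {
  schema <- pooled_table$schema
  if (is.null(vars)) vars <- names(schema)
  keep <- consensus_labels > 0L
  data <- pooled_table$data[keep, , drop = FALSE]
  lab <- consensus_labels[keep]
  out <- list()
  for (cl in sort(unique(lab))) {
    inc <- lab == cl
    if (!any(inc)) {
      warning("cluster ", cl, " is empty; row omitted")
      next
    }
    for (v in vars) {
      x <- data[[v]]
      spec <- schema[[v]]
      if (spec$kind == "continuous") {
        smry <- mean(x[inc])
        p <- tryCatch(
          stats::wilcox.test(x[inc], x[!inc], exact = FALSE)$p.value,
          error = function(e) NA_real_)
      } else {
        smry <- if (spec$kind == "nominal") {
          NA_real_ # level table goes through the chi-square only
        } else {
          mean(x[inc] > min(spec$levels))
        }
        tab <- table(factor(x, levels = spec$levels), inc)
        p <- tryCatch(
          suppressWarnings(stats::chisq.test(tab)$p.value),
          error = function(e) NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        variable = v, cluster = cl, n = sum(inc), summary = smry,
        p_value = p, stars = p_stars(p), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (bonferroni) {
    res$p_bonferroni <- pmin(res$p_value * nrow(res), 1)
  }
  res
}

#' Symptom-count distribution averaged over imputations
#'
#' Per-subject symptom counts are binned 0, 1, ..., 19, `">=20"` (the top
#' bin aggregates counts 20 through the number of items) and converted
#' to percentages; the percentage per bin is averaged across the m
#' completed datasets.
#'
#' @param iset An `imputation_set`.
#' @param top_bin Lower edge of the aggregated top bin (default 20).
#' @return Data frame `count` (character bins), `pct`.
#' @export
symptom_count_distribution <- function(iset, top_bin = 20L) {
  n_items <- length(schema_vars(iset$tables[[1L]]$schema, role = "symptom"))
  bins <- c(as.character(0:(top_bin - 1L)), paste0(">=", top_bin))
  pct <- matrix(0, length(bins), iset$m, dimnames = list(bins, NULL))
  for (i in seq_len(iset$m)) {
    cnt <- count_symptoms(iset$tables[[i]])
    binned <- ifelse(cnt >= top_bin, paste0(">=", top_bin), as.character(cnt))
    tab <- table(factor(binned, levels = bins))
    pct[, i] <- 100 * as.numeric(tab) / sum(tab)
  }
  data.frame(count = bins, pct = rowMeans(pct), stringsAsFactors = FALSE)
}
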
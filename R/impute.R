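#' Multiple imputation by chained equations with random forests
#'
#' Survey-role variables with missing cells are imputed iteratively: in
#' each sweep, each incomplete variable is regressed on all other
#' variables (random-forest classification for binary/ordinal/nominal,
#' random-forest regression for continuous) using the currently completed
#' data, and the missing cells are replaced by draws from the fitted
#' conditional — a class draw from the predicted probabilities for
#' categorical variables, a predictive-mean-matching draw (k nearest
#' donors by predicted value, default 5) for continuous ones.  Register
#' variables are never imputed.  The m chains run independently with RNG
#' streams derived from `(seed, table index)`.
#'
#' If a variable is missing for every subject of some cohort, that
#' variable's model drops `cohort` from its predictors, so its imputations
#' come from the distribution of the remaining cohorts.
#'
#' @param table A [cohort_table()] (register variables complete).
#' @param m Number of completed datasets (the study used 100; tests use
#'   fewer).
#' @param iterations Chained-equation sweeps per dataset (default 10).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 10, plenty for draws).
#' @param pmm_k Donor count for predictive mean matching.
#' @return An `imputation_set`: list with `m`, `tables` (list of complete
#'   `cohort_table`s), `seed`, `iterations`.
#' @export
mice_rf <- function(table, m = 5L, iterations = 10L, seed = 1L,
                    num_trees = 10L, pmm_k = 5L) {
  schema <- table$schema
  data <- table$data
  sv <- survey_vars(schema)
  miss_frac <- vapply(sv, function(v) mean(is.na(data[[v]])), numeric(1))
  targets <- sv[miss_frac > 0]
  if (!length(targets)) {
    out <- replicate(m, table, simplify = FALSE)
    return(structure(list(m = as.integer(m), tables = out,
                          seed = as.integer(seed),
                          iterations = as.integer(iterations)),
                     class = "imputation_set"))
  }
  if (any(miss_frac >= 1)) {
    stop("variable(s) missing for every subject: ",
         paste(sv[miss_frac >= 1], collapse = ", "))
  }
  targets <- targets[order(miss_frac[targets])] # ascending missingness

  # model frame: categorical as factors over declared levels
  all_vars <- names(schema)
  as_model_frame <- function(df) {
    mf <- df[all_vars]
    for (v in all_vars) {
      if (schema[[v]]$kind != "continuous") {
        mf[[v]] <- factor(mf[[v]], levels = schema_levels(schema, v))
      }
    }
    mf
  }

  # drop `cohort` from a target's predictors when some cohort observes
  # nothing of it
  drop_cohort <- vapply(targets, function(v) {
    if (!"cohort" %in% all_vars || v == "cohort") return(FALSE)
    any(tapply(is.na(data[[v]]), data$cohort, all))
  }, logical(1))
  names(drop_cohort) <- targets

  miss_idx <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- targets

  tables <- vector("list", m)
  for (t in seq_len(m)) {
    set.seed((seed + t * 10007L) %% .Machine$integer.max)
    filled <- data
    # initial fill: draw from observed marginal
    for (v in targets) {
      obs <- filled[[v]][!is.na(filled[[v]])]
      filled[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                           replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      mf <- as_model_frame(filled)
      for (v in targets) {
        idx <- miss_idx[[v]]
        preds <- setdiff(all_vars, v)
        if (drop_cohort[[v]]) preds <- setdiff(preds, "cohort")
        obs_rows <- setdiff(seq_len(nrow(mf)), idx)
        train <- mf[obs_rows, c(v, preds), drop = FALSE]
        train[[v]] <- if (schema[[v]]$kind == "continuous") {
          data[[v]][obs_rows]
        } else {
          droplevels(factor(data[[v]][obs_rows],
                            levels = schema_levels(schema, v)))
        }
        if (schema[[v]]$kind == "continuous") {
          fit <- ranger::ranger(
            x = train[preds], y = train[[v]], num.trees = num_trees,
            num.threads = 1L, seed = sample.int(1e6, 1)
          )
          p_obs <- fit$predictions # OOB predictions for donors
          p_mis <- stats::predict(fit, data = mf[idx, preds, drop = FALSE],
                                  num.threads = 1L)$predictions
          draw <- vapply(p_mis, function(p) {
            donors <- order(abs(p_obs - p))[seq_len(min(pmm_k, length(p_obs)))]
            train[[v]][sample(donors, 1L)]
          }, numeric(1))
          filled[[v]][idx] <- draw
        } else {
          fit <- ranger::ranger(
            x = train[preds], y = train[[v]], num.trees = num_trees,
            probability = TRUE, num.threads = 1L, seed = sample.int(1e6, 1)
          )
          pr <- stats::predict(fit, data = mf[idx, preds, drop = FALSE],
                               num.threads = 1L)$predictions
          lev <- colnames(pr)
          drawn <- apply(pr, 1L, function(p) sample(lev, 1L, prob = p))
          filled[[v]][idx] <- if (schema[[v]]$kind == "nominal") {
            drawn
          } else {
            as.integer(drawn)
          }
        }
        mf[[v]][idx] <- if (schema[[v]]$kind == "continuous") {
          filled[[v]][idx]
        } else {
          factor(filled[[v]][idx], levels = schema_levels(schema, v))
        }
      }
    }
    tables[[t]] <- cohort_table(filled, schema)
  }
  structure(list(m = as.integer(m), tables = tables, seed = as.integer(seed),
                 iterations = as.integer(iterations)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m = ", x$m, ", ", n_subjects(x$tables[[1L]]),
      " subjects, ", x$iterations, " iterations, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Descriptive pooling of an imputation set
#'
#' Collapses the m completed tables to one: per cell, the mode across
#' tables for binary/ordinal/nominal variables (ties broken toward the
#' lower-ordered level, deterministically) and the mean for continuous
#' variables.  Intended for descriptive statistics only — inferential
#' estimates are pooled with [rubin_pool()] instead.
#'
#' @param iset An `imputation_set`.
#' @return A single pooled `cohort_table`.
#' @export
pool_descriptive <- function(iset) {
  stopifnot(inherits(iset, "imputation_set"), iset$m >= 1L)
  if (iset$m == 1L) return(iset$tables[[1L]])
  schema <- iset$tables[[1L]]$schema
  out <- iset$tables[[1L]]$data
  for (v in names(schema)) {
    cols <- matrix(vapply(iset$tables, function(tb) as.character(tb$data[[v]]),
                          character(nrow(out))), nrow = nrow(out))
    if (schema[[v]]$kind == "continuous") {
      num <- matrix(as.numeric(cols), nrow = nrow(out))
      out[[v]] <- rowMeans(num)
    } else {
      lev <- as.character(schema_levels(schema, v))
      best_cnt <- rep(-1L, nrow(out))
      best_lev <- rep(NA_character_, nrow(out))
      for (l in lev) { # declared order => ties stay at the lower level
        cnt <- rowSums(cols == l)
        take <- cnt > best_cnt
        best_cnt[take] <- cnt[take]
        best_lev[take] <- l
      }
      out[[v]] <- if (schema[[v]]$kind == "nominal") best_lev else as.integer(best_lev)
    }
  }
  cohort_table(out, schema)
}

#' Persist / load an imputation set as CSV files plus a manifest
#'
#' One CSV per completed table (`imputation_001.csv`, ...) and a
#' `manifest.csv` recording m, iterations and seed.
#'
#' @param iset An `imputation_set`.
#' @param dir Output directory (created if absent).
#' @export
write_imputation_set <- function(iset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(iset$m)) {
    write_cohort(iset$tables[[i]], file.path(dir, sprintf("imputation_%03d.csv", i)))
  }
  utils::write.csv(
    data.frame(m = iset$m, iterations = iset$iterations, seed = iset$seed),
    file.path(dir, "manifest.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_imputation_set
#' @param schema Schema used to re-type the tables.
#' @export
read_imputation_set <- function(dir, schema) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  tables <- lapply(seq_len(man$m), function(i) {
    read_cohort(file.path(dir, sprintf("imputation_%03d.csv", i)), schema)
  })
  structure(list(m = man$m, tables = tables, seed = man$seed,
                 iterations = man$iterations),
            class = "imputation_set")
}
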
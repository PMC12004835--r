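#' Default Charlson comorbidity category map for ICD-10
#'
#' Classical Charlson categories expressed as 3-character ICD-10 code
#' prefixes with their integer weights, shipped as an editable structure.
#' The chronic pulmonary category is split so that asthma (J45-J46) and
#' COPD (J40-J44) are their own categories; the modified index used for
#' confounder adjustment excludes those two (they are adjusted for
#' individually instead).
#'
#' @return List with `categories` (named list of `prefixes` + `weight`)
#'   and `exclusions` (categories dropped from the modified score).
#' @export
default_cci_map <- function() {
  malignancy <- sprintf("C%02d", c(0:26, 30:34, 37:41, 43, 45:58, 60:76,
                                   81:85, 88, 90:97))
  metastatic <- sprintf("C%02d", 77:80)
  malignancy <- setdiff(malignancy, metastatic)
  categories <- list(
    myocardial_infarction = list(prefixes = c("I21", "I22"), weight = 1L),
    heart_failure = list(prefixes = "I50", weight = 1L),
    peripheral_vascular = list(prefixes = c("I70", "I71"), weight = 1L),
    cerebrovascular = list(prefixes = sprintf("I6%d", 0:9), weight = 1L),
    dementia = list(prefixes = c("F00", "F01", "F02", "F03", "G30"),
                    weight = 1L),
    copd = list(prefixes = sprintf("J4%d", 0:4), weight = 1L),
    asthma = list(prefixes = c("J45", "J46"), weight = 1L),
    chronic_pulmonary_other = list(prefixes = c("J47", sprintf("J6%d", 0:7)),
                                   weight = 1L),
    rheumatic = list(prefixes = c("M05", "M06", "M32", "M33", "M34"),
                     weight = 1L),
    peptic_ulcer = list(prefixes = c("K25", "K26", "K27", "K28"), weight = 1L),
    mild_liver = list(prefixes = c("B18", "K70", "K73", "K74"), weight = 1L),
    diabetes = list(prefixes = c("E10", "E11", "E13", "E14"), weight = 1L),
    hemiplegia = list(prefixes = c("G81", "G82"), weight = 2L),
    renal = list(prefixes = c("N18", "N19"), weight = 2L),
    malignancy = list(prefixes = malignancy, weight = 2L),
    severe_liver = list(prefixes = c("I85", "K72"), weight = 3L),
    metastatic_cancer = list(prefixes = metastatic, weight = 6L),
    aids = list(prefixes = c("B20", "B21", "B22", "B24"), weight = 6L)
  )
  all_pref <- unlist(lapply(categories, `[[`, "prefixes"))
  if (anyDuplicated(all_pref)) {
    stop("CCI map invalid: prefixes overlap across categories")
  }
  list(categories = categories, exclusions = c("asthma", "copd"))
}

valid_icd10 <- function(code) {
  grepl("^[A-Z][0-9]{2}(\\.?[0-9A-Z]{0,2})?$", code)
}

match_cci_categories <- function(codes, map) {
  hit <- character(0)
  for (nm in names(map$categories)) {
    pref <- map$categories[[nm]]$prefixes
    if (any(vapply(codes, function(cd) any(startsWith(cd, pref)), logical(1)))) {
      hit <- c(hit, nm)
    }
  }
  hit
}

#' Modified Charlson comorbidity score from ICD-10 records
#'
#' Considers specialist-care records dated in the calendar-year window
#' `[index_year - lookback, index_year]`.  A category counts once if any
#' in-window record code starts with one of its prefixes; the score is
#' the sum of weights over counted categories, excluding the configured
#' exclusion set (asthma and COPD by default, yielding the modified
#' index).
#'
#' @param records Data frame `subject_id`, `icd10`, `date`.
#' @param subject Subject identifier to score.
#' @param index_year Survey year anchoring the lookback window.
#' @param map Category map, see [default_cci_map()].
#' @param exclusions Categories to drop; defaults to the map's own
#'   exclusion set.
#' @param lookback Window length in years before `index_year` (default 11).
#' @return Integer score.
#' @export
compute_cci <- function(records, subject, index_year,
                        map = default_cci_map(),
                        exclusions = map$exclusions,
                        lookback = 11L) {
  rec <- records[records$subject_id == subject, , drop = FALSE]
  if (!nrow(rec)) return(0L)
  bad <- !valid_icd10(rec$icd10)
  if (any(bad)) {
    stop("malformed ICD-10 code '", rec$icd10[which(bad)[1L]],
         "' for subject ", subject)
  }
  yr <- as.integer(format(as.Date(rec$date), "%Y"))
  rec <- rec[yr >= index_year - lookback & yr <= index_year, , drop = FALSE]
  if (!nrow(rec)) return(0L)
  cats <- setdiff(match_cci_categories(rec$icd10, map), exclusions)
  if (!length(cats)) return(0L)
  sum(vapply(map$categories[cats], `[[`, integer(1), "weight"))
}

#' Score every subject at once
#'
#' Vectorised wrapper around the per-subject scoring rule.
#'
#' @param records Data frame `subject_id`, `icd10`, `date`.
#' @param subject_ids Subjects to score (scores 0 when no records).
#' @inheritParams compute_cci
#' @return Named integer vector of scores.
#' @export
cci_scores <- function(records, subject_ids, index_year,
                       map = default_cci_map(),
                       exclusions = map$exclusions, lookback = 11L) {
  bad <- !valid_icd10(records$icd10)
  if (any(bad)) {
    stop("malformed ICD-10 code '", records$icd10[which(bad)[1L]], "'")
  }
  yr <- as.integer(format(as.Date(records$date), "%Y"))
  rec <- records[yr >= index_year - lookback & yr <= index_year, , drop = FALSE]
  # map each record to its category (prefixes are non-overlapping)
  cat_of <- rep(NA_character_, nrow(rec))
  for (nm in names(map$categories)) {
    pref <- map$categories[[nm]]$prefixes
    hit <- vapply(rec$icd10, function(cd) any(startsWith(cd, pref)), logical(1))
    cat_of[hit & is.na(cat_of)] <- nm
  }
  keep <- !is.na(cat_of) & !(cat_of %in% exclusions)
  wt <- vapply(map$categories, `[[`, integer(1), "weight")
  scores <- stats::setNames(integer(length(subject_ids)), subject_ids)
  if (any(keep)) {
    per <- unique(data.frame(subject_id = rec$subject_id[keep],
                             category = cat_of[keep],
                             stringsAsFactors = FALSE))
    agg <- tapply(wt[per$category], per$subject_id, sum)
    idx <- intersect(names(agg), subject_ids)
    scores[idx] <- as.integer(agg[idx])
  }
  scores
}

#' Categorise a comorbidity score
#'
#' The analysis strata use three levels: 0, 1-2, and >= 3.
#'
#' @param score Non-negative integer score(s).
#' @return Character vector in `{"0", "1-2", ">=3"}`.
#' @export
cci_category <- function(score) {
  if (any(score < 0)) stop("CCI score cannot be negative")
  ifelse(score == 0, "0", ifelse(score <= 2, "1-2", ">=3"))
}

#' Flag asthma and COPD from self-report and register records
#'
#' A flag is raised when the subject self-reports a physician diagnosis
#' or carries an in-window specialist-care record with a J45/J46 (asthma)
#' or J40-J44 (COPD) prefix; either source suffices by default.
#'
#' @param records Data frame `subject_id`, `icd10`, `date`.
#' @param self_report Data frame `subject_id`, `asthma`, `copd`
#'   (logical); may be `NULL` to use register records only.
#' @param index_year Survey year anchoring the lookback window.
#' @param subject_ids Subjects to flag.
#' @param source `"both"` (default), `"register"`, or `"self_report"`.
#' @param lookback Window length in years (default 11).
#' @return Data frame `subject_id`, `asthma`, `copd` (logical).
#' @export
flag_asthma_copd <- function(records, self_report = NULL, index_year,
                             subject_ids = unique(records$subject_id),
                             source = c("both", "register", "self_report"),
                             lookback = 11L) {
  source <- match.arg(source)
  asthma <- copd <- stats::setNames(rep(FALSE, length(subject_ids)), subject_ids)
  if (source != "self_report" && nrow(records)) {
    yr <- as.integer(format(as.Date(records$date), "%Y"))
    rec <- records[yr >= index_year - lookback & yr <= index_year, , drop = FALSE]
    a_ids <- unique(rec$subject_id[startsWith(rec$icd10, "J45") |
                                     startsWith(rec$icd10, "J46")])
    c_ids <- unique(rec$subject_id[substr(rec$icd10, 1, 2) == "J4" &
                                     substr(rec$icd10, 3, 3) %in% as.character(0:4)])
    asthma[names(asthma) %in% a_ids] <- TRUE
    copd[names(copd) %in% c_ids] <- TRUE
  }
  if (source != "register" && !is.null(self_report)) {
    m <- match(subject_ids, self_report$subject_id)
    sr_a <- !is.na(m) & self_report$asthma[m] %in% TRUE
    sr_c <- !is.na(m) & self_report$copd[m] %in% TRUE
    asthma <- asthma | sr_a
    copd <- copd | sr_c
  }
  data.frame(subject_id = subject_ids, asthma = unname(asthma),
             copd = unname(copd), stringsAsFactors = FALSE)
}
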
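#' Cohort tables
#'
#' A cohort table pairs a subjects-by-variables data frame with the schema
#' that types it.  Binary and ordinal cells are stored as integer level
#' codes, nominal cells as character labels, continuous cells as numeric.
#' `NA` marks a missing survey cell; register-role columns must be
#' complete (register sources have near-complete coverage and are never
#' imputed).
#'
#' @param data Data frame with a `subject_id` column plus one column per
#'   schema variable.
#' @param schema A [resp_schema()].
#' @return A `cohort_table` object with elements `data` and `schema`.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "resp_schema"))
  if (!"subject_id" %in% names(data)) stop("data must have a subject_id column")
  if (anyDuplicated(data$subject_id)) stop("subject_id values must be unique")
  extra <- setdiff(names(data), c("subject_id", names(schema)))
  if (length(extra)) {
    stop("columns not declared in schema: ", paste(extra, collapse = ", "))
  }
  miss <- setdiff(names(schema), names(data))
  if (length(miss)) {
    stop("schema variables absent from data: ", paste(miss, collapse = ", "))
  }
  data <- data[, c("subject_id", names(schema)), drop = FALSE]
  for (v in names(schema)) {
    data[[v]] <- coerce_column(data[[v]], schema[[v]])
  }
  validate_cells(data, schema)
  structure(list(data = data, schema = schema), class = "cohort_table")
}

coerce_column <- function(x, spec) {
  switch(spec$kind,
    binary = ,
    ordinal = {
      if (is.character(x)) x[!nzchar(x)] <- NA
      suppressWarnings(as.integer(x))
    },
    nominal = {
      x <- as.character(x)
      x[!is.na(x) & !nzchar(x)] <- NA
      x
    },
    continuous = suppressWarnings(as.numeric(x))
  )
}

validate_cells <- function(data, schema) {
  for (v in names(schema)) {
    spec <- schema[[v]]
    x <- data[[v]]
    if (spec$role == "register" && anyNA(x)) {
      stop("register variable '", v, "' contains missing values; ",
           "register data are expected complete")
    }
    if (spec$kind %in% c("binary", "ordinal", "nominal")) {
      bad <- !is.na(x) & !(x %in% spec$levels)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop("invalid level '", x[i], "' for variable '", v,
             "' (subject ", data$subject_id[i], "); declared levels: ",
             paste(spec$levels, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " subjects x ",
      length(x$schema), " variables\n", sep = "")
  nmiss <- sum(is.na(x$data[, survey_vars(x$schema), drop = FALSE]))
  cat("  missing survey cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort table
#' @param table A `cohort_table`.
#' @export
n_subjects <- function(table) nrow(table$data)

#' Read a cohort CSV against a schema
#'
#' Expects a delimited text file with a header row naming `subject_id` and
#' every schema variable.  Empty cells are the missing marker.  Unknown
#' columns and out-of-range level codes are rejected with informative
#' errors.
#'
#' @param path File path.
#' @param schema A [resp_schema()].
#' @param delim Field delimiter (default comma).
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, schema, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          na.strings = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  cohort_table(df, schema)
}

#' Write a cohort table as CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f), schema)`
#' reproduces `x` cell for cell.  Missing cells are written as empty
#' fields.
#'
#' @param table A `cohort_table`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_cohort <- function(table, path, delim = ",") {
  utils::write.table(table$data, path, sep = delim, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Define an ordinal composite variable
#'
#' A composite collapses an ordered set of binary items (increasing
#' severity or chronicity) into one ordinal variable.  Under the
#' `highest_affirmative` policy the composite level is the 1-based index of
#' the highest affirmative source, or 0 when no source is affirmative, so
#' the composite has `length(sources) + 1` levels.
#'
#' @param target Name of the new ordinal variable.
#' @param sources Character vector of binary source variables, ordered by
#'   increasing severity.
#' @param policy Collapsing policy; only `"highest_affirmative"` is shipped,
#'   but the field is kept per rule so alternative policies can plug in.
#' @export
composite_rule <- function(target, sources, policy = "highest_affirmative") {
  stopifnot(is.character(target), length(target) == 1L,
            is.character(sources), length(sources) >= 1L)
  policy <- match.arg(policy)
  structure(list(target = target, sources = sources, policy = policy),
            class = "composite_rule")
}

#' Build ordinal composites from binary source items
#'
#' Applies each [composite_rule()] in turn: the new ordinal column is
#' appended as a symptom variable and the binary source columns are
#' removed.  A subject with all sources missing gets a missing composite;
#' partially missing sources are a contract violation (impute first or
#' build composites before injecting missingness).
#'
#' @param table A `cohort_table`.
#' @param rules List of [composite_rule()] objects.
#' @return A new `cohort_table` with composites in place of their sources.
#' @export
build_composites <- function(table, rules) {
  if (inherits(rules, "composite_rule")) rules <- list(rules)
  data <- table$data
  schema <- table$schema
  for (rule in rules) {
    unknown <- setdiff(rule$sources, names(schema))
    if (length(unknown)) {
      stop("composite rule '", rule$target, "' references unknown variable(s): ",
           paste(unknown, collapse = ", "))
    }
    kinds <- vapply(rule$sources, function(v) schema[[v]]$kind, character(1))
    if (!all(kinds == "binary")) {
      stop("composite sources must all be binary (rule '", rule$target, "')")
    }
    src <- as.matrix(data[, rule$sources, drop = FALSE])
    n_miss <- rowSums(is.na(src))
    partial <- n_miss > 0L & n_miss < length(rule$sources)
    if (any(partial)) {
      stop("subjects with partially missing sources for composite '",
           rule$target, "': ", paste(utils::head(data$subject_id[partial], 5L),
                                     collapse = ", "))
    }
    # highest affirmative source index; 0 when none affirmative
    lev <- apply(src, 1L, function(r) {
      if (anyNA(r)) return(NA_integer_)
      hits <- which(r == 1L)
      if (length(hits)) max(hits) else 0L
    })
    data <- data[, setdiff(names(data), rule$sources), drop = FALSE]
    data[[rule$target]] <- as.integer(lev)
    schema <- resp_schema(c(
      schema[setdiff(names(schema), rule$sources)],
      list(variable_spec(rule$target, kind = "ordinal", role = "symptom",
                         levels = 0:length(rule$sources)))
    ))
  }
  cohort_table(data, schema)
}

#' Count respiratory symptoms per subject
#'
#' A binary symptom item counts when affirmative (1); an ordinal symptom
#' variable counts when above its lowest level.  Symptom cells must be
#' complete — counting runs on observed or imputed data, never across
#' missing cells.
#'
#' @param table A `cohort_table`.
#' @return Integer vector, one count per subject, named by subject_id.
#' @export
count_symptoms <- function(table) {
  schema <- table$schema
  vars <- schema_vars(schema, role = "symptom")
  if (!length(vars)) stop("schema declares no symptom variables")
  m <- as.matrix(table$data[, vars, drop = FALSE])
  if (anyNA(m)) {
    stop("missing symptom cells; impute before counting symptoms")
  }
  affirm <- matrix(0L, nrow(m), ncol(m))
  for (j in seq_along(vars)) {
    spec <- schema[[vars[j]]]
    affirm[, j] <- if (spec$kind == "binary") {
      as.integer(m[, j] == 1L)
    } else {
      as.integer(m[, j] > min(spec$levels))
    }
  }
  counts <- as.integer(rowSums(affirm))
  names(counts) <- table$data$subject_id
  counts
}

#' Split a cohort into symptomatic and asymptomatic subsets
#'
#' The clustering stage runs on subjects reporting at least one
#' respiratory symptom; the asymptomatic remainder later serves as the
#' mortality reference group.
#'
#' @param table A `cohort_table` with complete symptom cells.
#' @return List with `cohort_table` elements `symptomatic` and
#'   `asymptomatic` (a partition of the input).
#' @export
eligibility_split <- function(table) {
  counts <- count_symptoms(table)
  sympt <- counts >= 1L
  if (!any(!sympt)) {
    warning("no asymptomatic subjects: reference group is empty")
  }
  list(
    symptomatic = subset_cohort(table, sympt),
    asymptomatic = subset_cohort(table, !sympt)
  )
}

subset_cohort <- function(table, idx) {
  out <- table
  out$data <- table$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
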
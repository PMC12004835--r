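#' Declare a survey or register variable
#'
#' A schema entry records everything the pipeline needs to know about a
#' column: its measurement kind, its ordered levels (for categorical
#' kinds), and its role in the analysis.  Symptom variables are the
#' clustering inputs; background variables are survey covariates subject to
#' imputation; register variables come from administrative sources and must
#' be complete.
#'
#' @param name Variable name, unique within a schema.
#' @param kind One of `"binary"`, `"ordinal"`, `"nominal"`, `"continuous"`.
#' @param role One of `"symptom"`, `"background"`, `"register"`.
#' @param levels Ordered level codes.  Binary variables are fixed to
#'   `c(0, 1)`; ordinal levels are integer codes in increasing order;
#'   nominal levels are character labels.  Ignored for continuous.
#' @return A `variable_spec` object.
#' @export
variable_spec <- function(name,
                          kind = c("binary", "ordinal", "nominal", "continuous"),
                          role = c("symptom", "background", "register"),
                          levels = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "binary") {
    if (!is.null(levels) && !identical(as.integer(levels), c(0L, 1L))) {
      stop("binary variable '", name, "' must have levels {0, 1}")
    }
    levels <- c(0L, 1L)
  } else if (kind == "ordinal") {
    if (is.null(levels) || length(levels) < 2L) {
      stop("ordinal variable '", name, "' needs >= 2 ordered levels")
    }
    levels <- as.integer(levels)
    if (anyNA(levels) || anyDuplicated(levels)) {
      stop("ordinal levels of '", name, "' must be distinct integer codes")
    }
  } else if (kind == "nominal") {
    if (is.null(levels) || length(levels) < 2L) {
      stop("nominal variable '", name, "' needs >= 2 levels")
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicate nominal levels in '", name, "'")
  } else {
    levels <- NULL
  }
  if (role == "symptom" && !kind %in% c("binary", "ordinal")) {
    stop("symptom variable '", name, "' must be binary or ordinal")
  }
  structure(list(name = name, kind = kind, role = role, levels = levels),
            class = "variable_spec")
}

#' Assemble a variable schema
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return A `resp_schema`: a named list of variable specs.
#' @export
resp_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "variable_spec")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop("all schema entries must be variable_spec objects")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate variable names in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(specs) <- nms
  structure(specs, class = "resp_schema")
}

#' @export
print.resp_schema <- function(x, ...) {
  cat("<resp_schema> ", length(x), " variables\n", sep = "")
  for (role in c("symptom", "background", "register")) {
    v <- schema_vars(x, role = role)
    if (length(v)) cat("  ", role, ": ", paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Variable names of a schema, optionally filtered
#'
#' @param schema A `resp_schema`.
#' @param role,kind Optional filters.
#' @return Character vector of variable names.
#' @export
schema_vars <- function(schema, role = NULL, kind = NULL) {
  keep <- rep(TRUE, length(schema))
  if (!is.null(role)) {
    keep <- keep & vapply(schema, function(s) s$role %in% role, logical(1))
  }
  if (!is.null(kind)) {
    keep <- keep & vapply(schema, function(s) s$kind %in% kind, logical(1))
  }
  names(schema)[keep]
}

#' Survey-role variables (symptom + background): the imputation targets
#' @param schema A `resp_schema`.
#' @export
survey_vars <- function(schema) schema_vars(schema, role = c("symptom", "background"))

schema_kind <- function(schema, var) schema[[var]]$kind
schema_levels <- function(schema, var) schema[[var]]$levels

#' Read / write a schema as a delimited config file
#'
#' The on-disk format is a CSV with columns `name`, `kind`, `role`,
#' `levels`, where `levels` joins the ordered level codes with `|`
#' (empty for continuous variables).
#'
#' @param path File path.
#' @return `read_schema` returns a `resp_schema`.
#' @export
read_schema <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "kind", "role", "levels")
  if (!all(need %in% names(df))) {
    stop("schema file must have columns: ", paste(need, collapse = ", "))
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    lv <- df$levels[i]
    lv <- if (is.na(lv) || !nzchar(lv)) NULL else strsplit(lv, "|", fixed = TRUE)[[1L]]
    variable_spec(df$name[i], kind = df$kind[i], role = df$role[i], levels = lv)
  })
  resp_schema(specs)
}

#' @rdname read_schema
#' @param schema A `resp_schema` to serialise.
#' @export
write_schema <- function(schema, path) {
  df <- data.frame(
    name = names(schema),
    kind = vapply(schema, `[[`, character(1), "kind"),
    role = vapply(schema, `[[`, character(1), "role"),
    levels = vapply(schema, function(s) {
      if (is.null(s$levels)) "" else paste(s$levels, collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
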
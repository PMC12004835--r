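#' Mixed-attribute dissimilarities for binary/ordinal/nominal data
#'
#' The clustering stage works on categorical attributes only.  Per
#' attribute j the level-to-level distance is the mismatch indicator for
#' binary and nominal attributes and the normalised rank difference
#' |rank(a) - rank(b)| / (L_j - 1) for an ordinal attribute with L_j
#' declared levels, so every attribute contributes at most weight w_j
#' (default 1) to the total.
#'
#' @name mixed_distance
NULL

# Encode the clustered attributes of a table: integer level indices plus
# per-attribute level distance matrices.  `vars` defaults to the symptom
# variables, the clustering inputs.
cluster_encode <- function(table, vars = NULL, weights = NULL) {
  schema <- table$schema
  if (is.null(vars)) vars <- schema_vars(schema, role = "symptom")
  if (!length(vars)) stop("no attributes to cluster on")
  kinds <- vapply(vars, function(v) schema[[v]]$kind, character(1))
  if (any(kinds == "continuous")) {
    stop("clustering handles binary/ordinal/nominal attributes only")
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(vars)), vars)
  X <- matrix(NA_integer_, n_subjects(table), length(vars),
              dimnames = list(NULL, vars))
  dist_mats <- vector("list", length(vars))
  names(dist_mats) <- vars
  for (j in seq_along(vars)) {
    v <- vars[j]
    lev <- schema_levels(schema, v)
    x <- table$data[[v]]
    if (anyNA(x)) stop("missing cells in '", v, "': cluster completed tables only")
    X[, j] <- match(x, lev)
    L <- length(lev)
    D <- if (kinds[j] == "ordinal" && L > 1L) {
      r <- seq_len(L) - 1L
      abs(outer(r, r, "-")) / (L - 1L)
    } else {
      1 - diag(L)
    }
    dist_mats[[j]] <- D * weights[[v]]
  }
  list(X = X, vars = vars, kinds = kinds,
       levels = lapply(vars, function(v) schema_levels(schema, v)),
       dist_mats = dist_mats, weights = weights)
}

# look up a level index, with a schema-mismatch error
level_index <- function(value, levels, var) {
  i <- match(value, levels)
  if (is.na(i)) {
    stop("level '", value, "' not declared for attribute '", var, "'")
  }
  i
}

#' Distance between two subjects on the clustered attributes
#'
#' Sum over attributes of the weighted per-attribute distance: mismatch
#' for binary/nominal, normalised rank difference for ordinal.
#'
#' @param x,y Named vectors (or single-row data frames) of attribute
#'   values; must be complete on the clustered attributes.
#' @param schema A [resp_schema()].
#' @param vars Attributes to compare; default all symptom variables.
#' @param weights Named per-attribute weights, default 1.
#' @return Non-negative scalar.
#' @export
point_point_distance <- function(x, y, schema, vars = NULL, weights = NULL) {
  if (is.data.frame(x)) x <- unlist(x[1L, ])
  if (is.data.frame(y)) y <- unlist(y[1L, ])
  if (is.null(vars)) vars <- schema_vars(schema, role = "symptom")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(vars)), vars)
  total <- 0
  for (v in vars) {
    xv <- x[[v]]; yv <- y[[v]]
    if (is.na(xv) || is.na(yv)) {
      stop("missing value on attribute '", v, "'; distances need complete data")
    }
    lev <- schema_levels(schema, v)
    d <- if (schema_kind(schema, v) == "ordinal") {
      abs(level_index(xv, lev, v) - level_index(yv, lev, v)) / (length(lev) - 1L)
    } else {
      as.numeric(xv != yv)
    }
    total <- total + weights[[v]] * d
  }
  total
}

#' Construct a cluster representative
#'
#' A representative summarises a cluster as one frequency vector per
#' attribute: entry c of `f[[j]]` is the probability mass the cluster
#' places on level c of attribute j.  Each vector must sum to 1.
#'
#' @param freqs Named list (one element per attribute) of named numeric
#'   vectors over that attribute's declared levels.
#' @return A `representative` object.
#' @export
representative <- function(freqs) {
  for (j in names(freqs)) {
    f <- freqs[[j]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop("frequency vector for '", j, "' must be non-negative and sum to 1")
    }
  }
  structure(list(freqs = freqs), class = "representative")
}

#' Dissimilarity between a subject and a cluster representative
#'
#' The expectation of [point_point_distance()] attribute-wise under the
#' representative's frequency vectors:
#' `sum_j w_j * sum_c f_jc * d_j(x_j, c)`.  For a binary attribute this
#' reduces to `1 - f_j[x_j]`.
#'
#' @param x Named vector of attribute values.
#' @param R A [representative()].
#' @param schema A [resp_schema()].
#' @param weights Named per-attribute weights, default 1.
#' @return Non-negative scalar.
#' @export
point_rep_dissimilarity <- function(x, R, schema, weights = NULL) {
  if (is.data.frame(x)) x <- unlist(x[1L, ])
  vars <- names(R$freqs)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(vars)), vars)
  total <- 0
  for (v in vars) {
    lev <- schema_levels(schema, v)
    f <- R$freqs[[v]]
    if (length(f) != length(lev) ||
        (!is.null(names(f)) && !all(names(f) == as.character(lev)))) {
      stop("representative frequencies for '", v,
           "' do not match the declared levels")
    }
    xi <- level_index(x[[v]], lev, v)
    d <- if (schema_kind(schema, v) == "ordinal") {
      r <- seq_along(lev) - 1L
      abs(r[xi] - r) / (length(lev) - 1L)
    } else {
      as.numeric(seq_along(lev) != xi)
    }
    total <- total + weights[[v]] * sum(f * d)
  }
  total
}
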
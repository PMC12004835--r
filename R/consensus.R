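#' Exact minimum-cost assignment (bitmask dynamic program)
#'
#' Solves the square assignment problem exactly in O(2^k * k) time and
#' O(2^k) memory, ample for the cluster counts used here (k <= 20).
#'
#' @param cost k x k cost matrix.
#' @return Integer vector `p` with row i assigned to column `p[i]`.
#' @keywords internal
solve_assignment <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  if (k > 20L) stop("assignment solver supports k <= 20")
  nmask <- bitwShiftL(1L, k)
  f <- rep(Inf, nmask)
  from <- integer(nmask) # column added to reach this mask
  f[1L] <- 0
  bitcount <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) > 0L), integer(1))
  for (mask in 0:(nmask - 2L)) {
    if (!is.finite(f[mask + 1L])) next
    i <- bitcount[mask + 1L] + 1L # next row to assign
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) {
        nm <- bitwOr(mask, bit)
        val <- f[mask + 1L] + cost[i, j]
        if (val < f[nm + 1L]) { f[nm + 1L] <- val; from[nm + 1L] <- j }
      }
    }
  }
  p <- integer(k)
  mask <- nmask - 1L
  for (i in k:1) {
    j <- from[mask + 1L]
    p[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  p
}

#' Align one label vector to a reference
#'
#' Finds the permutation of cluster indices that maximises the total
#' contingency-table overlap between `other` and `reference` (optimal
#' assignment on the k x k agreement matrix).  Applying the returned
#' permutation to `other` makes its labels comparable to the reference,
#' which a majority vote across imputations presupposes.
#'
#' @param reference,other Integer label vectors in 1..k over the same
#'   subjects, in the same order.
#' @param k Common number of clusters.
#' @return Integer permutation `perm`: old label `j` becomes `perm[j]`.
#' @export
align_labels <- function(reference, other, k) {
  stopifnot(length(reference) == length(other))
  if (any(reference < 1L | reference > k) || any(other < 1L | other > k)) {
    stop("labels must lie in 1..k (differing cluster counts cannot be aligned)")
  }
  agree <- matrix(0L, k, k)
  tab <- table(factor(other, levels = 1:k), factor(reference, levels = 1:k))
  agree[] <- tab
  # maximise overlap = minimise negated overlap; rows = old label,
  # columns = new label
  solve_assignment(-agree)
}

#' Apply a label permutation
#' @param labels Integer labels in 1..k.
#' @param perm Permutation from [align_labels()].
#' @export
apply_permutation <- function(labels, perm) perm[labels]

#' Majority-vote consensus across an ensemble of clusterings
#'
#' Each ensemble member is first aligned to the reference member (the
#' first by default), then every subject receives the modal aligned
#' label; ties break toward the lowest label index, deterministically.
#' The agreement fraction is the modal count divided by the ensemble
#' size.
#'
#' @param ensemble Matrix (subjects x members) or list of label vectors
#'   in 1..k over the same subjects.
#' @param k Number of clusters; default inferred.
#' @param align Align members to the reference first (default TRUE).
#' @param reference Index of the reference member (default 1).
#' @return List with `labels` (consensus), `agreement` (per subject) and
#'   `aligned` (the aligned ensemble matrix).
#' @export
majority_vote <- function(ensemble, k = NULL, align = TRUE, reference = 1L) {
  if (is.list(ensemble)) ensemble <- do.call(cbind, ensemble)
  if (!is.matrix(ensemble) || ncol(ensemble) < 1L) {
    stop("ensemble must contain at least one label vector")
  }
  m <- ncol(ensemble)
  if (is.null(k)) k <- max(ensemble)
  aligned <- ensemble
  if (align && m > 1L) {
    for (i in setdiff(seq_len(m), reference)) {
      perm <- align_labels(ensemble[, reference], ensemble[, i], k)
      aligned[, i] <- apply_permutation(ensemble[, i], perm)
    }
  }
  counts <- matrix(0L, nrow(ensemble), k)
  for (c in seq_len(k)) counts[, c] <- rowSums(aligned == c)
  labels <- max.col(counts, ties.method = "first")
  agreement <- counts[cbind(seq_len(nrow(counts)), labels)] / m
  list(labels = labels, agreement = agreement, aligned = aligned)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to
#' relabeling), about 0 for independent ones.
#'
#' @param a,b Label vectors over the same subjects.
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(ifelse(nij == expected, 1, 0))
  (nij - expected) / denom
}
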
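#' Locality-sensitive hashing partition of the clustered attributes
#'
#' Subjects are encoded numerically (one-hot for binary/nominal
#' attributes, normalised rank in `[0, 1]` for ordinal), mean-centred,
#' and projected on `n_bits` random hyperplanes; the sign pattern is the
#' subject's signature and subjects sharing a signature share a bucket.
#' Similar subjects collide with high probability, so the buckets seed
#' the cluster initialisation.
#'
#' @param table A [cohort_table()] complete on the clustered attributes.
#' @param n_bits Signature length (>= 1); at most `2^n_bits` buckets.
#' @param seed Integer seed for the hyperplane draw.
#' @param vars Attributes to hash; default the symptom variables.
#' @return An `lsh_index`: list with `n_bits`, `hyperplanes`,
#'   `signatures` (per subject) and `buckets` (signature -> subject
#'   indices).
#' @export
lsh_partition <- function(table, n_bits = 6L, seed = 1L, vars = NULL) {
  if (n_bits < 1L) stop("n_bits must be >= 1")
  enc <- cluster_encode(table, vars)
  lsh_partition_enc(enc, n_bits, seed)
}

lsh_numeric_encoding <- function(enc) {
  n <- nrow(enc$X)
  cols <- list()
  for (j in seq_along(enc$vars)) {
    L <- length(enc$levels[[j]])
    if (enc$kinds[j] == "ordinal") {
      cols[[j]] <- (enc$X[, j] - 1L) / (L - 1L)
    } else {
      oh <- matrix(0, n, L)
      oh[cbind(seq_len(n), enc$X[, j])] <- 1
      cols[[j]] <- oh
    }
  }
  E <- do.call(cbind, cols)
  scale(E, center = TRUE, scale = FALSE)
}

lsh_partition_enc <- function(enc, n_bits, seed) {
  set.seed(seed)
  E <- lsh_numeric_encoding(enc)
  H <- matrix(stats::rnorm(ncol(E) * n_bits), ncol(E), n_bits)
  S <- (E %*% H) >= 0
  sig <- apply(S, 1L, function(b) paste(as.integer(b), collapse = ""))
  buckets <- split(seq_len(nrow(E)), sig)
  structure(list(n_bits = as.integer(n_bits), hyperplanes = H,
                 signatures = sig, buckets = buckets),
            class = "lsh_index")
}

# per-group frequency profile: list of per-attribute frequency vectors
group_freqs <- function(enc, idx) {
  lapply(seq_along(enc$vars), function(j) {
    tabulate(enc$X[idx, j], nbins = length(enc$levels[[j]])) / length(idx)
  })
}

# expected distance between two frequency profiles: sum_j f1' D_j f2
profile_dissimilarity <- function(f1, f2, dist_mats) {
  total <- 0
  for (j in seq_along(dist_mats)) {
    total <- total + as.numeric(f1[[j]] %*% dist_mats[[j]] %*% f2[[j]])
  }
  total
}

#' Seed cluster representatives from LSH buckets
#'
#' Non-empty buckets, sorted by size, form the seed groups.  With more
#' groups than k, the two groups with the smallest expected
#' representative-to-representative distance are merged greedily until k
#' remain.  With fewer, the largest group is split on its
#' highest-entropy attribute (modal level vs the rest) until k exist.
#' Each seed group's attribute frequency vectors become a representative.
#'
#' @param index An `lsh_index` from [lsh_partition()].
#' @param k Number of clusters (<= number of subjects).
#' @param table The clustered [cohort_table()].
#' @param vars Attributes used when the index was built.
#' @return List of k [representative()] objects.
#' @export
init_representatives <- function(index, k, table, vars = NULL) {
  enc <- cluster_encode(table, vars)
  freqs <- init_representatives_enc(index, k, enc)
  lapply(freqs, function(f) {
    representative(stats::setNames(
      lapply(seq_along(enc$vars), function(j) {
        stats::setNames(f[[j]], as.character(enc$levels[[j]]))
      }), enc$vars))
  })
}

init_representatives_enc <- function(index, k, enc) {
  if (k > nrow(enc$X)) stop("k exceeds the number of subjects")
  groups <- index$buckets[order(-lengths(index$buckets))]
  groups <- unname(groups[lengths(groups) > 0L])

  # split largest group on its highest-entropy attribute until k groups
  while (length(groups) < k) {
    sizes <- lengths(groups)
    splittable <- which(sizes >= 2L)
    if (!length(splittable)) stop("cannot form ", k, " groups: too few subjects")
    g <- splittable[which.max(sizes[splittable])]
    idx <- groups[[g]]
    ent <- vapply(seq_along(enc$vars), function(j) {
      p <- tabulate(enc$X[idx, j], nbins = length(enc$levels[[j]])) / length(idx)
      p <- p[p > 0]
      -sum(p * log(p))
    }, numeric(1))
    j <- which.max(ent)
    cnt <- tabulate(enc$X[idx, j], nbins = length(enc$levels[[j]]))
    modal <- which.max(cnt)
    a <- idx[enc$X[idx, j] == modal]
    b <- idx[enc$X[idx, j] != modal]
    if (!length(b)) { # constant attribute everywhere: arbitrary halving
      half <- seq_len(floor(length(idx) / 2))
      a <- idx[half]; b <- idx[-half]
    }
    groups[[g]] <- a
    groups[[length(groups) + 1L]] <- b
    groups <- groups[order(-lengths(groups))]
  }

  profs <- lapply(groups, function(idx) group_freqs(enc, idx))
  sizes <- lengths(groups)

  # greedy merge of the nearest pair until k groups remain
  while (length(profs) > k) {
    g <- length(profs)
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(g - 1L)) {
      for (b in (a + 1L):g) {
        d <- profile_dissimilarity(profs[[a]], profs[[b]], enc$dist_mats)
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    a <- best[1L]; b <- best[2L]
    wa <- sizes[a] / (sizes[a] + sizes[b])
    profs[[a]] <- lapply(seq_along(profs[[a]]), function(j) {
      wa * profs[[a]][[j]] + (1 - wa) * profs[[b]][[j]]
    })
    sizes[a] <- sizes[a] + sizes[b]
    profs <- profs[-b]; sizes <- sizes[-b]
  }
  profs
}

# frequency profiles (list over attributes of k x L matrices) -> n x k cost
assignment_cost <- function(enc, F) {
  n <- nrow(enc$X)
  k <- nrow(F[[1L]])
  cost <- matrix(0, n, k)
  for (j in seq_along(enc$vars)) {
    M <- enc$dist_mats[[j]] %*% t(F[[j]]) # L x k
    cost <- cost + M[enc$X[, j], , drop = FALSE]
  }
  cost
}

update_freqs <- function(enc, labels, k) {
  lapply(seq_along(enc$vars), function(j) {
    L <- length(enc$levels[[j]])
    cnt <- matrix(0, k, L)
    for (c in seq_len(k)) {
      idx <- labels == c
      if (any(idx)) cnt[c, ] <- tabulate(enc$X[idx, j], nbins = L) / sum(idx)
    }
    cnt
  })
}

#' Fit the LSH-initialised k-representatives model
#'
#' Alternates assignment (each subject to the representative with the
#' smallest [point_rep_dissimilarity()], ties broken toward the lowest
#' cluster index) with representative updates (attribute frequency
#' vectors of the assigned members).  Iteration stops when no label
#' changes, when `max_iter` is reached, or when a frequency update would
#' raise the within-cluster objective — the update is then reverted and
#' the model declared converged, which keeps the logged objective trace
#' non-increasing.  Clusters emptied by an assignment are reseeded with
#' the subject farthest from its current representative.
#'
#' @param table A [cohort_table()] complete on the clustered attributes.
#' @param k Number of clusters (>= 1, <= number of subjects).
#' @param vars Attributes to cluster on; default the symptom variables.
#' @param weights Named per-attribute weights, default 1.
#' @param n_bits LSH signature length for initialisation.
#' @param max_iter Iteration cap (default 100).
#' @param seed Integer seed (hyperplanes and tie-free determinism).
#' @return A `cluster_model`: `k`, `representatives` (list of
#'   [representative()]), `labels` (1..k, named by subject), `objective`,
#'   `n_iter`, `converged`, `trace` (objective after each assignment),
#'   `seed`.
#' @export
lshkp_fit <- function(table, k, vars = NULL, weights = NULL,
                      n_bits = 6L, max_iter = 100L, seed = 1L) {
  enc <- cluster_encode(table, vars, weights)
  n <- nrow(enc$X)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of subjects")

  F <- if (k == 1L) {
    list2matrixF(list(group_freqs(enc, seq_len(n))))
  } else {
    index <- lsh_partition_enc(enc, n_bits, seed)
    list2matrixF(init_representatives_enc(index, k, enc))
  }

  labels <- rep(0L, n)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cost <- assignment_cost(enc, F)
    new_labels <- max.col(-cost, ties.method = "first")
    # reseed empty clusters with the farthest-from-representative subject
    # (donors only from clusters that keep at least one member)
    repeat {
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (!length(empty)) break
      e <- empty[1L]
      sizes <- tabulate(new_labels, nbins = k)
      d_own <- cost[cbind(seq_len(n), new_labels)]
      d_own[sizes[new_labels] < 2L] <- -Inf
      far <- which.max(d_own)
      new_labels[far] <- e
      for (j in seq_along(F)) {
        F[[j]][e, ] <- 0
        F[[j]][e, enc$X[far, j]] <- 1
      }
      cost <- assignment_cost(enc, F)
    }
    obj <- sum(cost[cbind(seq_len(n), new_labels)])
    trace <- c(trace, obj)
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    if (iter >= max_iter) break
    F_new <- update_freqs(enc, labels, k)
    obj_new <- sum(assignment_cost(enc, F_new)[cbind(seq_len(n), labels)])
    if (obj_new > obj + 1e-9) { converged <- TRUE; break }
    F <- F_new
  }

  reps <- lapply(seq_len(k), function(c) {
    representative(stats::setNames(
      lapply(seq_along(enc$vars), function(j) {
        stats::setNames(F[[j]][c, ], as.character(enc$levels[[j]]))
      }), enc$vars))
  })
  names(labels) <- table$data$subject_id
  structure(list(k = k, representatives = reps, labels = labels,
                 objective = trace[length(trace)], n_iter = iter,
                 converged = converged, trace = trace, vars = enc$vars,
                 weights = enc$weights, seed = seed),
            class = "cluster_model")
}

list2matrixF <- function(profs) {
  k <- length(profs)
  lapply(seq_along(profs[[1L]]), function(j) {
    do.call(rbind, lapply(profs, `[[`, j))
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", x$k, ", n = ", length(x$labels),
      ", objective = ", format(x$objective, digits = 6),
      ", iterations = ", x$n_iter,
      if (!x$converged) " (not converged)", "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Recompute a model's objective from its labels and representatives
#'
#' @param model A `cluster_model`.
#' @param table The table it was fitted on.
#' @return Sum over subjects of the dissimilarity to the assigned
#'   representative.
#' @export
model_objective <- function(model, table) {
  enc <- cluster_encode(table, model$vars, model$weights)
  F <- list2matrixF(lapply(model$representatives, function(r) {
    lapply(r$freqs, unname)
  }))
  cost <- assignment_cost(enc, F)
  sum(cost[cbind(seq_along(model$labels), unname(model$labels))])
}

#' Mean silhouette width under the mixed-attribute distance
#'
#' Standard silhouette with [point_point_distance()] as the metric,
#' computed exactly via per-cluster level counts (no pairwise matrix).
#' Subjects in singleton clusters score 0.
#'
#' @param table A [cohort_table()] complete on the clustered attributes.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @param vars,weights As in [lshkp_fit()].
#' @return Mean silhouette in `[-1, 1]`; per-subject widths in attribute
#'   `"widths"`.
#' @export
silhouette_mixed <- function(table, labels, vars = NULL, weights = NULL) {
  enc <- cluster_encode(table, vars, weights)
  labels <- as.integer(labels)
  n <- nrow(enc$X)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette needs at least 2 clusters")
  k <- max(ks)
  sizes <- tabulate(labels, nbins = k)
  # S[i, c] = total distance from subject i to every member of cluster c
  S <- matrix(0, n, k)
  for (j in seq_along(enc$vars)) {
    L <- length(enc$levels[[j]])
    cnt <- matrix(0, k, L)
    for (c in ks) cnt[c, ] <- tabulate(enc$X[labels == c, j], nbins = L)
    M <- enc$dist_mats[[j]] %*% t(cnt) # L x k
    S <- S + M[enc$X[, j], , drop = FALSE]
  }
  own <- labels
  a <- S[cbind(seq_len(n), own)] / pmax(sizes[own] - 1L, 1L)
  Sb <- S
  Sb[cbind(seq_len(n), own)] <- Inf
  for (c in seq_len(k)) {
    if (sizes[c] > 0L) Sb[, c] <- Sb[, c] / sizes[c] else Sb[, c] <- Inf
  }
  Sb[cbind(seq_len(n), own)] <- Inf
  b <- apply(Sb, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0
  s[sizes[own] == 1L] <- 0
  out <- mean(s)
  attr(out, "widths") <- s
  out
}

#' Scan cluster counts and suggest one
#'
#' Fits the model for each k in `k_range` (default 2..10, the published
#' scan) on the same data and seed schedule, reporting the objective,
#' mean silhouette and cluster sizes.  The suggestion is the k with the
#' largest silhouette (ties toward smaller k); the final choice remains
#' the caller's, as cluster-count selection also weighs subject-matter
#' interpretability.
#'
#' @param table A [cohort_table()].
#' @param k_range Integer vector of cluster counts within `[2, n - 1]`.
#' @param vars,weights,n_bits,max_iter,seed As in [lshkp_fit()].
#' @return List with `metrics` (one row per k) and `suggested_k`.
#' @export
scan_k <- function(table, k_range = 2:10, vars = NULL, weights = NULL,
                   n_bits = 6L, max_iter = 100L, seed = 1L) {
  if (!length(k_range)) stop("k_range is empty")
  n <- n_subjects(table)
  if (any(k_range < 2L) || any(k_range >= n)) {
    stop("k_range must lie within [2, n - 1]")
  }
  rows <- lapply(k_range, function(k) {
    fit <- lshkp_fit(table, k, vars = vars, weights = weights,
                     n_bits = n_bits, max_iter = max_iter, seed = seed)
    sil <- silhouette_mixed(table, fit$labels, vars = vars, weights = weights)
    sizes <- tabulate(fit$labels, nbins = k)
    data.frame(k = k, objective = fit$objective, silhouette = as.numeric(sil),
               n_iter = fit$n_iter, converged = fit$converged,
               min_size = min(sizes), max_size = max(sizes))
  })
  metrics <- do.call(rbind, rows)
  best <- which(metrics$silhouette == max(metrics$silhouette))
  suggested <- metrics$k[best[which.min(metrics$k[best])]]
  list(metrics = metrics, suggested_k = suggested)
}
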
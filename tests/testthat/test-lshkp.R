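test_that("LSH hashing is deterministic and bucket count is bounded", {
  tab <- toy_cohort(40, seed = 5)
  idx <- lsh_partition(tab, n_bits = 4, seed = 2)
  # identical rows share a signature
  dup <- tab
  dup$data[2, schema_vars(tab$schema, role = "symptom")] <-
    dup$data[1, schema_vars(tab$schema, role = "symptom")]
  idx2 <- lsh_partition(dup, n_bits = 4, seed = 2)
  expect_identical(idx2$signatures[1], idx2$signatures[2])

  idx1 <- lsh_partition(tab, n_bits = 1, seed = 2)
  expect_lte(length(idx1$buckets), 2)
  expect_error(lsh_partition(tab, n_bits = 0), "n_bits")

  # every subject lands in exactly one bucket
  expect_setequal(unlist(idx$buckets), seq_len(40))
})

test_that("LSH buckets are pure on well-separated planted clusters", {
  sep <- make_separated_cohort(n = 1500, seed = 3)
  idx <- lsh_partition(sep$table, n_bits = 8, seed = 4)
  purity <- vapply(idx$buckets, function(b) {
    max(table(sep$truth[b])) / length(b)
  }, numeric(1))
  # size-weighted majority-truth fraction
  w <- lengths(idx$buckets) / sum(lengths(idx$buckets))
  expect_gt(sum(w * purity), 0.9)
})

test_that("bucket seeding reduces to bucket profiles and global profile", {
  tab <- toy_cohort(30, seed = 6)
  idx <- lsh_partition(tab, n_bits = 3, seed = 1)
  k <- length(idx$buckets)
  reps <- init_representatives(idx, k, tab)
  expect_length(reps, k)
  # the largest bucket's representative is its raw frequency profile
  big <- idx$buckets[[which.max(lengths(idx$buckets))]]
  f_wheeze <- mean(tab$data$wheeze[big] == 1L)
  found <- vapply(reps, function(r) r$freqs$wheeze[["1"]], numeric(1))
  expect_true(any(abs(found - f_wheeze) < 1e-12))

  one <- init_representatives(idx, 1, tab)
  expect_equal(one[[1]]$freqs$wheeze[["1"]], mean(tab$data$wheeze == 1L))
  expect_error(init_representatives(idx, 31, tab), "exceeds")
})

test_that("greedy merging joins the pair found by exhaustive search", {
  tab <- toy_cohort(24, seed = 7)
  # hand-built index with three groups; merging to k = 2 must join the
  # argmin-dissimilarity pair over all three pairs
  groups <- list(1:8, 9:16, 17:24)
  fake <- structure(list(n_bits = 2L, hyperplanes = NULL,
                         signatures = NULL, buckets = groups),
                    class = "lsh_index")
  reps3 <- init_representatives(fake, 3, tab)
  sch <- tab$schema
  pair_d <- function(a, b) {
    # expected distance between two frequency profiles, brute-forced
    vars <- names(a$freqs)
    tot <- 0
    for (v in vars) {
      lv <- schema_levels(sch, v)
      for (i in seq_along(lv)) for (j in seq_along(lv)) {
        d <- if (schema_kind(sch, v) == "ordinal") {
          abs(i - j) / (length(lv) - 1)
        } else as.numeric(i != j)
        tot <- tot + a$freqs[[v]][i] * b$freqs[[v]][j] * d
      }
    }
    unname(tot)
  }
  ds <- c(`12` = pair_d(reps3[[1]], reps3[[2]]),
          `13` = pair_d(reps3[[1]], reps3[[3]]),
          `23` = pair_d(reps3[[2]], reps3[[3]]))
  best <- names(which.min(ds))
  merged <- init_representatives(fake, 2, tab)
  # the merged representative is the size-weighted average of the pair;
  # identify which pair was merged by matching frequency profiles
  avg <- function(a, b) (unlist(a$freqs) + unlist(b$freqs)) / 2
  cands <- list(`12` = avg(reps3[[1]], reps3[[2]]),
                `13` = avg(reps3[[1]], reps3[[3]]),
                `23` = avg(reps3[[2]], reps3[[3]]))
  hit <- vapply(cands, function(cf) {
    any(vapply(merged, function(m) {
      max(abs(unlist(m$freqs) - cf)) < 1e-12
    }, logical(1)))
  }, logical(1))
  expect_true(hit[[best]])
})

test_that("fitting recovers two far-separated profiles exactly", {
  prof <- matrix(c(rep(0.95, 15), rep(0.05, 16),
                   rep(0.05, 15), rep(0.95, 16)), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, default_symptom_items()))
  cfg <- generator_config(n_subjects = 600, asymptomatic_fraction = 0,
                          mixing = c(0.5, 0.5), symptom_profiles = prof,
                          survival_model = default_survival_model(2),
                          seed = 12)
  gen <- generate_cohort(cfg)
  fit <- lshkp_fit(gen$table, k = 2, seed = 3)
  expect_equal(adjusted_rand(fit$labels, gen$truth$cluster), 1.0)
  expect_true(fit$converged)
})

test_that("k = 1 yields the global profile objective", {
  tab <- toy_cohort(25, seed = 9)
  fit <- lshkp_fit(tab, k = 1, seed = 1)
  expect_true(all(fit$labels == 1L))
  brute <- sum(vapply(seq_len(25), function(i) {
    point_rep_dissimilarity(tab$data[i, ], fit$representatives[[1]],
                            tab$schema)
  }, numeric(1)))
  expect_equal(fit$objective, brute, tolerance = 1e-9)
})

test_that("the objective trace never increases and is recomputable", {
  for (s in 1:5) {
    sep <- make_separated_cohort(n = 500, seed = s)
    fit <- lshkp_fit(sep$table, k = 5, seed = s + 50)
    expect_true(all(diff(fit$trace) <= 1e-9))
    expect_equal(model_objective(fit, sep$table), fit$objective,
                 tolerance = 1e-9)
    # converged models have no empty cluster and unit-sum representatives
    expect_identical(sort(unique(unname(fit$labels))), 1:5)
    for (r in fit$representatives) {
      sums <- vapply(r$freqs, sum, numeric(1))
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
})

test_that("labels are invariant to subject reordering", {
  sep <- make_separated_cohort(n = 400, seed = 17)
  fit <- lshkp_fit(sep$table, k = 5, seed = 5)
  perm <- sample(n_subjects(sep$table))
  shuffled <- sep$table
  shuffled$data <- shuffled$data[perm, , drop = FALSE]
  rownames(shuffled$data) <- NULL
  fit2 <- lshkp_fit(shuffled, k = 5, seed = 5)
  # same partition up to label names once mapped back by subject id
  back <- fit2$labels[names(fit$labels)]
  expect_equal(adjusted_rand(back, fit$labels), 1.0)
})

test_that("silhouette agrees with the classical pairwise computation", {
  sep <- make_separated_cohort(n = 120, seed = 8)
  fit <- lshkp_fit(sep$table, k = 3, seed = 2)
  ours <- silhouette_mixed(sep$table, fit$labels)
  D <- brute_distance_matrix(sep$table)
  ref <- cluster::silhouette(unname(fit$labels), dmatrix = D)
  expect_equal(as.numeric(ours), mean(ref[, "sil_width"]), tolerance = 1e-9)
  w <- attr(ours, "widths")
  expect_true(all(w >= -1 & w <= 1))
  expect_error(silhouette_mixed(sep$table, rep(1L, n_subjects(sep$table))),
               "at least 2")
})

test_that("silhouette separates planted blocks and is null on noise", {
  sep <- make_separated_cohort(n = 1200, seed = 4)
  s_true <- silhouette_mixed(sep$table, sep$truth)
  expect_gt(as.numeric(s_true), 0.35)

  # homogeneous data with random labels: silhouette near zero
  prof <- matrix(0.5, 1, 31, dimnames = list(NULL, default_symptom_items()))
  cfg <- generator_config(n_subjects = 2000, asymptomatic_fraction = 0,
                          mixing = 1, symptom_profiles = prof,
                          survival_model = default_survival_model(1),
                          seed = 10)
  tab <- generate_cohort(cfg)$table
  set.seed(11)
  s_null <- silhouette_mixed(tab, sample(1:2, 2000, TRUE))
  expect_lt(abs(as.numeric(s_null)), 0.05)
})

test_that("the k scan reports the grid and suggests the planted count", {
  sep <- make_separated_cohort(n = 1200, seed = 14)
  sc <- scan_k(sep$table, k_range = 2:10, seed = 3)
  expect_identical(sc$metrics$k, 2:10)
  expect_identical(nrow(sc$metrics), 9L)
  expect_identical(sc$suggested_k, 5L)
  # objective non-increasing in k on the same data/seed schedule
  expect_true(all(diff(sc$metrics$objective) <= 1e-9))
  expect_error(scan_k(sep$table, k_range = integer(0)), "empty")
})
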
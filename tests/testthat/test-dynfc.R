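zmat <- function(n = 10, tt = 300, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * tt), n, dimnames = list(default_roi_set()$names[1:n],
                                                NULL))
  zscore_series(x)
}

test_that("z-scoring is exact, affine-invariant and idempotent", {
  z <- zmat()
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)

  set.seed(2)
  x <- matrix(rnorm(10 * 100), 10)
  rownames(x) <- default_roi_set()$names
  x2 <- 3.7 * x + 11
  expect_equal(zscore_series(x), zscore_series(x2), tolerance = 1e-12)
  expect_equal(zscore_series(zscore_series(x)), zscore_series(x),
               tolerance = 1e-12)

  # alternating row against the direct formula: sd = sqrt(T/(T-1))
  a <- matrix(rep(c(1, -1), 50), 1)
  rownames(a) <- "S1HLL"
  expect_equal(as.numeric(zscore_series(a)),
               as.numeric(a) / sqrt(100 / 99), tolerance = 1e-12)

  x[3, ] <- 5
  expect_error(zscore_series(x), "M2L")
})

test_that("cofluctuation sums reproduce the Pearson matrix exactly", {
  z <- zmat(10, 300, seed = 3)
  co <- cofluctuation_series(z, "a1")
  expect_equal(ncol(co$values), 55)
  tt <- ncol(z)
  recon <- devectorize_symmetric(colSums(co$values) / (tt - 1), n = 10)
  expect_lt(max(abs(recon - cor(t(z)))), 1e-10)
  # unit diagonal: every C_ii sums to T-1
  diag_cols <- paste(rownames(z), rownames(z), sep = "~")
  expect_lt(max(abs(colSums(co$values[, diag_cols]) / (tt - 1) - 1)),
            1e-12)
})

test_that("cohort concatenation stacks frames and keeps provenance", {
  z1 <- zmat(10, 100, seed = 4)
  z2 <- zmat(10, 150, seed = 5)
  co <- concatenate_cohort(list(cofluctuation_series(z1, "a1"),
                                cofluctuation_series(z2, "a2")))
  expect_equal(nrow(co$values), 250)
  expect_equal(sum(co$frames$acquisition_id == "a1"), 100)
  expect_equal(co$frames$frame[101], 1)

  z3 <- zmat(9, 50, seed = 6)
  expect_error(concatenate_cohort(list(cofluctuation_series(z1, "a"),
                                       cofluctuation_series(z3, "b"))),
               "ROI")
})

test_that("outlier scores equal the brute-force pairwise computation", {
  set.seed(7)
  for (tt in c(50, 200, 500)) {
    v <- matrix(rnorm(tt * 55), tt)
    os <- outlier_scores(v)
    expect_lt(max(abs(os$mean_distance - mean_l1_bruteforce(v))), 1e-9)
  }
  # identical frames: all scores equal, none removed
  v0 <- matrix(1, 20, 55)
  os0 <- outlier_scores(v0)
  expect_true(all(os0$keep))
  expect_equal(diff(range(os0$scores)), 0)

  # one wild frame in a long series is removed
  v <- matrix(rnorm(1000 * 55), 1000)
  v[123, ] <- v[123, ] * 100
  os <- outlier_scores(v)
  expect_false(os$keep[123])
  expect_gt(mean(os$keep), 0.99)
})

test_that("L1 k-means honors its algorithmic contract", {
  set.seed(8)
  x <- matrix(rnorm(200 * 12), 200)
  # K = 1: centroid is the coordinate-wise median
  m1 <- kmeans_l1(x, 1, restarts = 3, seed = 2)
  expect_equal(as.numeric(m1$centroids), apply(x, 2, median),
               tolerance = 1e-12)

  m <- kmeans_l1(x, 4, restarts = 10, seed = 2)
  # objective non-increasing within the winning run
  expect_true(all(diff(m$objective_trace) <= 1e-9))
  # final assignment is L1-nearest-centroid, checked exhaustively
  d <- sapply(seq_len(4), function(k) {
    colSums(abs(t(x) - m$centroids[k, ]))
  })
  expect_equal(m$labels, apply(d, 1, which.min), ignore_attr = TRUE)
  expect_equal(m$total_within_l1, sum(d[cbind(seq_len(200), m$labels)]),
               tolerance = 1e-9)
  # state 1 is the most frequent
  expect_equal(m$counts, sort(m$counts, decreasing = TRUE))
  # determinism
  m2 <- kmeans_l1(x, 4, restarts = 10, seed = 2)
  expect_identical(m$labels, m2$labels)
  expect_identical(m$centroids, m2$centroids)
  expect_error(kmeans_l1(x, 201, restarts = 1, seed = 1), "exceeds")
})

test_that("well-separated blobs are recovered perfectly across seeds", {
  set.seed(9)
  centers <- matrix(c(rep(0, 12), rep(12, 12), rep(c(0, 12), 6)), 3,
                    byrow = TRUE)
  truth <- rep(1:3, each = 120)
  x <- centers[truth, ] + matrix(rnorm(360 * 12, 0, 0.1), 360)
  for (s in 1:20) {
    m <- kmeans_l1(x, 3, restarts = 5, seed = s)
    # perfect recovery up to permutation
    tab <- table(truth, m$labels)
    expect_equal(sort(apply(tab, 1, max)), sort(rowSums(tab)))
  }
})

test_that("Duda-Hart split test behaves on Gaussian references", {
  # single Gaussian blob: no split suggested in most seeded runs
  zero_splits <- 0
  for (s in 1:15) {
    set.seed(s)
    x <- matrix(rnorm(2000 * 10), 2000)
    dh <- duda_hart_k(x, k_max = 1, restarts = 5, seed = s)
    if (dh$table$split_count[1] == 0) zero_splits <- zero_splits + 1
  }
  expect_gte(zero_splits, 14)

  # two 10-sigma-separated blobs: K = 1 must split, K = 2 is selected
  set.seed(77)
  x2 <- rbind(matrix(rnorm(600 * 10), 600),
              matrix(rnorm(600 * 10, mean = 10), 600))
  dh2 <- duda_hart_k(x2, k_max = 3, restarts = 5, seed = 3)
  expect_equal(dh2$table$split_count[1], 1)
  expect_equal(dh2$selected_k, 2)
})

test_that("occurrence rates sum to one and attribute frames correctly", {
  cfg <- quick_sim_config(600)
  co <- simulate_cohort(cfg, 3, 1, c("15C", "25C"), seed = 61)
  pre <- preprocess_cohort(co$acquisitions)
  ok <- vapply(pre$clean, function(x) x$status == "ok", logical(1))
  series <- lapply(pre$clean[ok], function(cs) {
    cofluctuation_series(zscore_series(cs), cs$source_id)
  })
  cofl <- filter_outliers(concatenate_cohort(series))
  m <- kmeans_l1(cofl, 4, restarts = 5, seed = 3)
  occ <- occurrence_rates(m, cofl$frames, co$manifest)
  sums <- tapply(occ$rate, occ$acquisition_id, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_equal(nrow(occ), 4 * sum(ok))

  # single-state labeling: rate 1 for state 1, 0 elsewhere
  m1 <- m
  m1$labels <- rep(1L, length(m$labels))
  occ1 <- occurrence_rates(m1, cofl$frames, co$manifest)
  expect_true(all(occ1$rate[occ1$state == 1] == 1))
  expect_true(all(occ1$rate[occ1$state != 1] == 0))
})

test_that("animal-state homogeneity table matches the contingency oracle", {
  cfg <- quick_sim_config(500, animal_sd = 0)
  co <- simulate_cohort(cfg, 4, 1, "25C", seed = 71)
  pre <- preprocess_cohort(co$acquisitions)
  series <- lapply(pre$clean, function(cs) {
    cofluctuation_series(zscore_series(cs), cs$source_id)
  })
  cofl <- concatenate_cohort(series)
  m <- kmeans_l1(cofl, 3, restarts = 5, seed = 4)
  h <- animal_state_homogeneity(m, cofl$frames, co$manifest)
  expect_equal(unname(colSums(h$composition)), rep(1, 3),
               tolerance = 1e-12)
  cst <- suppressWarnings(stats::chisq.test(h$counts, correct = FALSE))
  expect_equal(h$chisq, unname(cst$statistic), tolerance = 1e-10)
  expect_equal(h$df, unname(cst$parameter))

  # two animals with identical label streams contribute 50% of each state
  frames <- data.frame(acquisition_id = rep(c("x1", "x2"), each = 50),
                       frame = c(1:50, 1:50))
  man <- data.frame(acquisition_id = c("x1", "x2"),
                    animal_id = c("mA", "mB"), condition = "25C",
                    fs_hz = 2.5, path = "")
  mm <- list(k = 2, labels = rep(rep(1:2, 25), 2))
  h2 <- animal_state_homogeneity(mm, frames, man)
  expect_true(all(abs(h2$composition - 0.5) < 1e-12))
})

test_that("occurrence-rate statistics flag planted effects, not nulls", {
  # build occurrence tables from ground-truth labels: this isolates the
  # mixed-model layer from the clustering layer
  occ_from_gt <- function(co) {
    k <- length(co$config$templates)
    rows <- lapply(names(co$ground_truth), function(id) {
      st <- co$ground_truth[[id]]$state_sequence
      man <- co$manifest[co$manifest$acquisition_id == id, ]
      data.frame(animal_id = man$animal_id, condition = man$condition,
                 acquisition_id = id, state = seq_len(k),
                 rate = tabulate(st, k) / length(st))
    })
    do.call(rbind, rows)
  }
  base <- default_base_occupancy()
  # planted effect: weak state much more frequent at 25C
  eff <- sim_config(frames_per_acq = 800)
  eff$base_occupancy[["25C"]] <- c(0.60, rep(0.40 / 6, 6))
  eff$base_occupancy[["35C"]] <- c(0.45, rep(0.55 / 6, 6))
  co <- simulate_cohort(eff, 6, 2, c("25C", "35C"), seed = 81)
  res <- compare_occurrence(occ_from_gt(co))
  expect_identical(res$omnibus$status[1], "ok")
  expect_lt(res$omnibus$p_omnibus[1], 0.05)
  s1 <- res$pairwise[res$pairwise$state == 1, ]
  expect_true(s1$significant)
  # estimate sign: rate higher in 25C (condition_b = 35C minus 25C < 0)
  expect_lt(s1$estimate, 0)

  # single condition: untestable status
  co1 <- simulate_cohort(quick_sim_config(300), 3, 1, "25C", seed = 82)
  res1 <- compare_occurrence(occ_from_gt(co1))
  expect_true(all(res1$omnibus$status == "untestable"))
})

test_that("state alignment finds the best permutation", {
  tps <- make_default_templates()
  tv <- t(sapply(tps, function(tp) {
    vectorize_symmetric(tp$covariance)$values
  }))
  perm <- c(3L, 1L, 7L, 2L, 6L, 4L, 5L)
  fake <- list(k = 7, centroids = tv[perm, ] + 0.01)
  al <- align_states_to_templates(fake, tps)
  expect_identical(al$assignment, perm)
  expect_true(all(al$correlations > 0.99))
})
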
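test_that("correlation matrix matches the sums-of-products oracle", {
  # identical rows correlate at 1, a row and its negation at -1
  x <- matrix(rnorm(5 * 3), 3, byrow = TRUE)
  x <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ])
  cm <- correlation_matrix(x)
  expect_equal(cm$values["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cm$values["a", "c"], -1, tolerance = 1e-12)

  # 3 ROIs x 5 frames against the direct formula
  set.seed(9)
  y <- matrix(rnorm(15), 3, dimnames = list(c("r1", "r2", "r3"), NULL))
  cm2 <- correlation_matrix(y)$values
  for (i in 1:3) {
    for (j in 1:3) {
      xi <- y[i, ] - mean(y[i, ])
      xj <- y[j, ] - mean(y[j, ])
      oracle <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      expect_lt(abs(cm2[i, j] - oracle), 1e-12)
    }
  }
  validate_corr_matrix(cm2)

  # zero-variance ROI named in the error
  y[2, ] <- 7
  expect_error(correlation_matrix(y), "r2")
})

test_that("Fisher transform has the closed form and clipping contract", {
  expect_identical(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_true(is.finite(fisher_transform(1)))
  expect_equal(inverse_fisher(fisher_transform(1)), 1 - 1e-7,
               tolerance = 1e-9)
  r <- seq(-0.999999, 0.999999, length.out = 101)
  expect_lt(max(abs(inverse_fisher(fisher_transform(r)) - r)), 1e-9)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(0.01)$adjusted, 0.01)
  # boundary: all five rejected because p_(5) = 0.05 <= 5*0.05/5
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  # step-up: largest k with p_(k) <= k q / m is 5, so all adjusted = 0.05
  expect_equal(bh$adjusted, rep(0.05, 5))
  oracle <- bh_oracle(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)
  expect_equal(bh$adjusted, oracle$adjusted)

  set.seed(5)
  for (i in 1:200) {
    m <- sample(45, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    q <- runif(1, 0.01, 0.2)
    got <- benjamini_hochberg(p, q)
    want <- bh_oracle(p, q)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    # rejection sets agree except exactly at the adjusted == q boundary
    boundary <- abs(want$adjusted - q) < 1e-12
    expect_identical(got$reject[!boundary], want$reject[!boundary])
    # order invariance
    o <- sample(m)
    expect_equal(benjamini_hochberg(p[o], q)$adjusted, want$adjusted[o],
                 tolerance = 1e-12)
  }
})

test_that("mixed model reduces to the two-sample t-test without animal
           variance", {
  # with no true animal variance the REML fit collapses (singular) in most
  # replicates and the model degenerates to OLS = the pooled t-test; when
  # sampling noise yields a positive variance estimate the Satterthwaite p
  # legitimately differs, so the exact comparison targets collapsed fits
  set.seed(13)
  n_collapsed <- 0
  for (i in 1:10) {
    d <- make_edge_obs(n_animals = 4, obs_per_cond = 2, animal_sd = 0)
    r <- edge_mixed_model(d, c("25C", "15C"))
    if (identical(r$fit_method, "ols_fallback")) {
      n_collapsed <- n_collapsed + 1
      tt <- stats::t.test(z ~ condition, data = d, var.equal = TRUE)
      expect_lt(abs(r$p_raw - tt$p.value), 0.01)
    }
  }
  expect_gte(n_collapsed, 3)
})

test_that("mixed model handles untestable designs explicitly", {
  d <- make_edge_obs(n_animals = 1, obs_per_cond = 3)
  expect_identical(edge_mixed_model(d, c("25C", "15C"))$status,
                   "untestable")
  d2 <- make_edge_obs()
  expect_identical(edge_mixed_model(d2, c("25C", "35C"))$status,
                   "untestable")  # 35C absent
})

test_that("mixed model detects a planted Fisher-scale shift with power", {
  set.seed(17)
  p <- replicate(120, {
    d <- make_edge_obs(n_animals = 4, obs_per_cond = 2, shift = 0.5)
    edge_mixed_model(d, c("25C", "15C"))$p_raw
  })
  expect_gte(mean(p < 0.05), 0.8)
})

test_that("condition contrast assembles symmetric matrices and the
           45-edge BH family", {
  cfg <- quick_sim_config(400)
  co <- simulate_cohort(cfg, 4, 2, c("15C", "25C"), seed = 23)
  pre <- preprocess_cohort(co$acquisitions)
  obs <- edge_observations(pre$clean, co$manifest)
  expect_equal(length(unique(obs$edge)), 45)
  cc <- compare_conditions(obs, c("25C", "15C"), q = 0.05)
  expect_equal(cc$n_tested, 45)
  expect_equal(nrow(cc$results), 45)
  expect_true(isSymmetric(cc$significance))
  expect_true(isSymmetric(unname(cc$delta_z)))
  expect_true(all(is.na(diag(cc$delta_z))))
  expect_true(all(cc$results$p_adjusted >= cc$results$p_raw - 1e-12))
})

test_that("label-shuffled null cohorts rarely produce significant edges", {
  # same generator for both condition labels: any flagged edge is a false
  # positive; BH at q = 0.05 keeps cohort-level flags rare
  cfg <- quick_sim_config(300, animal_sd = 0.2)
  cfg$base_occupancy[["15C"]] <- cfg$base_occupancy[["25C"]]
  n_flagged <- 0
  set.seed(29)
  for (i in 1:15) {
    co <- simulate_cohort(cfg, 4, 2, c("15C", "25C"), seed = 300 + i)
    pre <- preprocess_cohort(co$acquisitions)
    obs <- edge_observations(pre$clean, co$manifest)
    cc <- compare_conditions(obs, c("25C", "15C"), q = 0.05)
    if (any(cc$results$significant)) n_flagged <- n_flagged + 1
  }
  expect_lte(n_flagged, 3)
})

test_that("planted connectivity differences between conditions are
           recovered", {
  # cold condition draws from the strong-dichotomy template, neutral from
  # the weak template: the SM-block and SM-hypothalamus edges must light up
  roi <- default_roi_set()
  tps <- make_default_templates(roi)
  cfg <- sim_config(roi = roi, templates = tps[c(1, 7)],
                    base_occupancy = list(`25C` = c(1, 0),
                                          `15C` = c(0, 1)),
                    transition_stickiness = 0, animal_sd = 0.1,
                    frames_per_acq = 500, artifact_rate = 0,
                    drift_amplitude = 0.2, global_amplitude = 0.2)
  co <- simulate_cohort(cfg, 5, 2, c("15C", "25C"), seed = 41)
  pre <- preprocess_cohort(co$acquisitions,
                           scrub_config(remove_global = FALSE))
  obs <- edge_observations(pre$clean, co$manifest)
  cc <- compare_conditions(obs, c("25C", "15C"), q = 0.05)
  sm <- roi_group_idx(roi, "somatomotor")
  hy <- roi_group_idx(roi, "hypothalamus")
  truly_changed <- rbind(t(utils::combn(sm, 2)),
                         as.matrix(expand.grid(sm, hy)))
  hit <- cc$significance[truly_changed]
  expect_gte(mean(hit), 0.7)
  # direction: SM block strengthens, SM-hypothalamus weakens in cold
  expect_gt(mean(cc$delta_z[t(utils::combn(sm, 2))]), 0)
  expect_lt(mean(cc$delta_z[as.matrix(expand.grid(sm, hy))]), 0)
})

test_that("condition mean matrices average per-acquisition correlations", {
  cfg <- quick_sim_config(300)
  co <- simulate_cohort(cfg, 2, 2, "25C", seed = 51)
  pre <- preprocess_cohort(co$acquisitions)
  mm <- condition_mean_matrix(pre$clean, co$manifest, "25C")
  mats <- lapply(pre$clean, function(cs) correlation_matrix(cs)$values)
  expect_equal(mm, Reduce(`+`, mats) / length(mats), tolerance = 1e-12)
  expect_error(condition_mean_matrix(pre$clean, co$manifest, "35C"),
               "35C")
})
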
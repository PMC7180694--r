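test_that("simulation is byte-identical under a fixed seed", {
  cfg <- drift_sim_config(n_classes = 2, n_sensors = 4, n_batches = 3,
                          samples_per_cell = 5, seed = 42)
  s1 <- simulate_enose(cfg)
  s2 <- simulate_enose(cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$eval_labels, s2$eval_labels)
})

test_that("source batch is labeled, later batches carry only hidden truth", {
  s <- simulate_enose(drift_sim_config(n_batches = 4, samples_per_cell = 3,
                                       seed = 7))
  src <- s$batch_ids == 1
  expect_true(all(!is.na(s$labels[src])))
  expect_true(all(is.na(s$labels[!src])))
  expect_true(all(!is.na(s$eval_labels[!src])))
  expect_true(all(s$roles[!src] == "target"))
})

test_that("zero drift and zero noise reproduce identical responses across batches", {
  cfg <- separated_config(seed = 3, noise_sd = 0,
                          batch_gain_drift = rep(1, 3),
                          batch_offset_drift = rep(0, 3),
                          concentration_grid = c(100))
  s <- simulate_enose(cfg)
  lab <- ifelse(is.na(s$labels), s$eval_labels, s$labels)
  for (g in unique(lab)) {
    rows <- s$features[lab == g, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2L, rows[1, ]))), 1e-12)
  }
})

test_that("well-separated gains give a perfect nearest-mean source fit", {
  s <- simulate_enose(separated_config(seed = 5))
  src <- s$batch_ids == 1
  clf <- classifier_nearest_mean()
  m <- clf$fit(s$features[src, ], s$labels[src])
  expect_equal(accuracy(s$labels[src], clf$predict(m, s$features[src, ])), 1.0)
})

test_that("without drift, cell means agree across batches within noise", {
  spc <- 30
  cfg <- separated_config(seed = 9, noise_sd = 0.5, samples_per_cell = spc,
                          batch_gain_drift = rep(1, 3),
                          batch_offset_drift = rep(0, 3),
                          concentration_grid = c(200))
  s <- simulate_enose(cfg)
  lab <- ifelse(is.na(s$labels), s$eval_labels, s$labels)
  tol <- 3 * 0.5 / sqrt(spc)
  for (g in unique(lab)) {
    ms <- sapply(sort(unique(s$batch_ids)), function(b) {
      colMeans(s$features[lab == g & s$batch_ids == b, , drop = FALSE])
    })
    expect_lt(max(abs(ms - rowMeans(ms))), 3 * tol)
  }
})

test_that("wider concentration spread increases dependence on the level kernel", {
  for (seed in 0:4) {
    hs <- sapply(list(c(50, 400), c(10, 1000)), function(rng) {
      s <- simulate_enose(drift_sim_config(
        n_batches = 2, samples_per_cell = 20, seed = seed,
        concentration_range = rng))
      src <- s$batch_ids == 1
      lv <- concentration_levels(s$concentrations[src])
      Y <- build_concentration_features(lv, src[src], sum(src))
      hsic_estimate(gram(s$features[src, ]), concentration_kernel(Y))
    })
    expect_gt(hs[2], hs[1])
  }
})

test_that("configuration validation rejects inconsistent instruments", {
  expect_error(drift_sim_config(n_classes = 0), "n_classes")
  expect_error(drift_sim_config(concentration_range = c(10, 1)), "range")
  expect_error(drift_sim_config(response_gain = matrix(1, 2, 2)),
               "response_gain")
  expect_error(drift_sim_config(batch_gain_drift = c(1, 2)),
               "batch_gain_drift")
  expect_error(drift_sim_config(noise_sd = -1), "noise_sd")
})
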
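test_that("accuracy is the fraction of agreeing labels", {
  expect_equal(accuracy(1:5, 1:5), 1.0)
  expect_equal(accuracy(rep(1, 4), rep(2, 4)), 0.0)
  expect_equal(accuracy(c(rep(1, 41), rep(1, 4)),
                        c(rep(1, 41), rep(2, 4))), 41 / 45)
  expect_error(accuracy(1:3, 1:4), "mismatch")
})

test_that("the protocol refuses degenerate batch structures", {
  s <- rand_sample_set(41, n = 10, m = 3, n_batches = 1)
  expect_error(run_batch_protocol(s), "at least 2 batches")

  s2 <- conceal_batches(rand_sample_set(42, n = 10, m = 3, n_batches = 2),
                        1)   # conceal the source batch instead
  expect_error(run_batch_protocol(s2), "fully labeled")
})

test_that("separable classes without drift or noise score 1.0 on every batch", {
  s <- simulate_enose(separated_config(seed = 6, noise_sd = 0,
                                       batch_gain_drift = rep(1, 3),
                                       batch_offset_drift = rep(0, 3)))
  for (m in c("baseline", "micf", "micf_ifld")) {
    r <- run_batch_protocol(s, method = m,
                            classifier = classifier_nearest_mean())
    expect_true(all(r$per_batch$accuracy == 1.0))
    expect_equal(r$average_accuracy, 1.0)
  }
})

test_that("the reported average is the unweighted per-batch mean", {
  s <- simulate_enose(drift_sim_config(n_batches = 4, samples_per_cell = 8,
                                       seed = 10))
  r <- run_batch_protocol(s, method = "micf",
                          classifier = classifier_nearest_mean())
  expect_equal(r$average_accuracy, mean(r$per_batch$accuracy),
               tolerance = 1e-12)
  expect_equal(r$per_batch$n_correct / r$per_batch$n, r$per_batch$accuracy)
  expect_setequal(r$per_batch$batch, 2:4)
})

test_that("hidden target labels never influence fitting (firewall)", {
  s <- simulate_enose(drift_sim_config(n_batches = 3, samples_per_cell = 10,
                                       seed = 11))
  r1 <- run_batch_protocol(s, method = "micf_ifld",
                           classifier = classifier_nearest_mean(), seed = 1)
  # corrupt the hidden truth: predictions must be unchanged, scores not
  s_bad <- s
  tgt <- which(s_bad$roles == "target")
  s_bad$eval_labels[tgt] <- ((s_bad$eval_labels[tgt]) %% 3L) + 1L
  r2 <- run_batch_protocol(s_bad, method = "micf_ifld",
                           classifier = classifier_nearest_mean(), seed = 1)
  expect_identical(r2$predictions, r1$predictions)
  expect_false(isTRUE(all.equal(r2$per_batch$accuracy,
                                r1$per_batch$accuracy)))
})

test_that("pooled-target adaptation reports the same batches", {
  s <- simulate_enose(drift_sim_config(n_batches = 3, samples_per_cell = 8,
                                       seed = 12))
  r <- run_batch_protocol(s, method = "micf",
                          classifier = classifier_nearest_mean(),
                          pool_targets = TRUE)
  expect_setequal(r$per_batch$batch, 2:3)
  expect_true(all(r$per_batch$accuracy >= 0 & r$per_batch$accuracy <= 1))
})

test_that("archive-dialect directories run end-to-end", {
  d <- withr::local_tempdir()
  s <- simulate_enose(separated_config(seed = 13, n_batches = 3))
  for (b in 1:3) {
    write_uci_drift_file(subset_samples_for_test(s, s$batch_ids == b),
                         file.path(d, sprintf("batch%d.dat", b)))
  }
  r <- run_uci_protocol(d, method = "micf_ifld",
                        classifier = classifier_nearest_mean())
  expect_s3_class(r, "protocol_result")
  expect_equal(nrow(r$per_batch), 2L)
  expect_named(r$per_batch, c("batch", "n", "n_correct", "accuracy"))
  expect_equal(r$average_accuracy, mean(r$per_batch$accuracy))
})

test_that("MICF model serialization round-trips through JSON", {
  Kx <- rand_psd(6, seed = 14)
  Ky <- matrix(0, 6, 6)
  fit <- fit_micf(Kx, Ky, mu = 2, h = 3)
  fit$kernel_spec <- kernel_spec("rbf", bandwidth = 1.5)
  fit$level_map <- stats::setNames(1:3L, c(2, 4, 6))
  f <- withr::local_tempfile(fileext = ".json")
  write_micf_model(fit, f)
  back <- read_micf_model(f)
  expect_equal(back$W, unname(fit$W))
  expect_equal(back$mu, 2)
  expect_equal(back$h, 3L)
  expect_equal(back$eigenvalues, fit$eigenvalues)
  expect_equal(back$kernel_spec$bandwidth, 1.5)
  expect_equal(unname(back$level_map), 1:3)
})
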
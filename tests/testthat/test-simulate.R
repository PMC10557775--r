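test_that("default design matches the two-group serum time-course layout", {
  sim <- simulate_expression(sim_config(n_genes = 40, seed = 1))
  expect_equal(nrow(sim$samples), 14 * 4 * 2)
  expect_equal(sort(unique(sim$samples$time_h)), seq(32, 58, 2))
  expect_equal(ncol(sim$expression) - 1, 112)
  expect_equal(nrow(sim$expression), 40)
  expect_setequal(unique(sim$samples$group), c("young", "old"))
  expect_equal(length(unique(paste(sim$samples$group, sim$samples$subject))), 8)
  # no missing values, all finite
  mat <- as.matrix(sim$expression[-1])
  expect_true(all(is.finite(mat)))
  expect_true(all(is.finite(as.matrix(sim$truth[-(1:2)]))))
})

test_that("class assignment is deterministic by index and matches fractions", {
  cfg <- sim_config(n_genes = 40, frac_both = 0.25, frac_young_only = 0.1,
                    frac_old_only = 0.05, seed = 2)
  sim <- simulate_expression(cfg)
  expect_equal(sim$truth$class,
               rep(c("both", "young_only", "old_only", "neither"),
                   c(10, 4, 2, 24)))
  # identical classes under another seed
  sim2 <- simulate_expression(sim_config(n_genes = 40, frac_both = 0.25,
                                         frac_young_only = 0.1,
                                         frac_old_only = 0.05, seed = 99))
  expect_identical(sim$truth$class, sim2$truth$class)
  # amplitude is zero exactly where the class excludes rhythmicity
  expect_true(all((sim$truth$amp_young == 0) ==
                    (sim$truth$class %in% c("old_only", "neither"))))
  expect_true(all((sim$truth$amp_old == 0) ==
                    (sim$truth$class %in% c("young_only", "neither"))))
  expect_true(all(sim$truth$peak_young >= 0 & sim$truth$peak_young < 24))
})

test_that("zero-noise values equal the deterministic cosine curve", {
  cfg <- sim_config(n_genes = 3, frac_both = 1, frac_young_only = 0,
                    frac_old_only = 0, noise_sd = 0, subject_offset_sd = 0,
                    mesor_shift_sd = 0, phase_shift_sd = 0, seed = 3)
  sim <- simulate_expression(cfg)
  mat <- as.matrix(sim$expression[-1])
  tr <- sim$truth
  w <- 2 * pi / 24
  for (j in seq_len(nrow(sim$samples))) {
    g <- sim$samples$group[j]
    M <- if (g == "young") tr$mesor_young else tr$mesor_old
    A <- if (g == "young") tr$amp_young else tr$amp_old
    P <- if (g == "young") tr$peak_young else tr$peak_old
    expect_equal(unname(mat[, j]), M + A * cos(w * (sim$samples$time_h[j] - P)),
                 tolerance = 1e-12)
  }
})

test_that("simulation is seed-deterministic", {
  a <- simulate_expression(sim_config(n_genes = 20, seed = 7))
  b <- simulate_expression(sim_config(n_genes = 20, seed = 7))
  c <- simulate_expression(sim_config(n_genes = 20, seed = 8))
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expression, c$expression))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(timepoints = c(32, 34, 36)), "4 timepoints")
  expect_error(sim_config(timepoints = c(32, 32, 36, 40)), "increasing")
  expect_error(sim_config(frac_both = 0.8, frac_young_only = 0.4), "sum")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(simulate_wearable(n_subjects_per_group = 0), "positive")
  expect_error(simulate_wearable(bin_minutes = 7), "divide 60")
})

test_that("cosinor fits recover planted parameters from near-noiseless data", {
  cfg <- sim_config(n_genes = 200, frac_both = 1, frac_young_only = 0,
                    frac_old_only = 0, amplitude_range = c(0.5, 1),
                    noise_sd = 0.05, subject_offset_sd = 0,
                    mesor_shift_sd = 0, phase_shift_sd = 0, seed = 11)
  sim <- simulate_expression(cfg)
  mat <- as.matrix(sim$expression[-1])
  young <- sim$samples$group == "young"
  ok <- vapply(seq_len(nrow(mat)), function(i) {
    f <- cosinor_fit(sim$samples$time_h[young], mat[i, young])
    dpk <- abs(f$peak_hour - sim$truth$peak_young[i])
    dpk <- min(dpk, 24 - dpk)
    abs(f$mesor - sim$truth$mesor_young[i]) < 0.02 &&
      abs(f$amplitude - sim$truth$amp_young[i]) < 0.05 && dpk < 0.25
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("wearable simulator produces exact cosines without noise", {
  wd <- simulate_wearable(n_subjects_per_group = 1, days = 1,
                          bin_minutes = 30,
                          mesor = c(young = 10, old = 10),
                          amplitude = c(young = 2, old = 2),
                          peak_hour = c(young = 14, old = 14),
                          noise_sd = 0, level_jitter_sd = 0,
                          phase_jitter_sd = 0, seed = 1)
  one <- wd[wd$subject == "young_01", ]
  expect_equal(one$time_h[1], 0.25)  # first bin midpoint
  expect_equal(one$value, 10 + 2 * cos(2 * pi * (one$time_h - 14) / 24),
               tolerance = 1e-12)
})

test_that("wearable bin counts and fitted peaks behave as planted", {
  wd <- simulate_wearable(n_subjects_per_group = 2, days = 1, bin_minutes = 1,
                          noise_sd = 0, level_jitter_sd = 0,
                          phase_jitter_sd = 0, seed = 2)
  expect_equal(nrow(wd), 1440 * 4)
  expect_equal(sum(wd$subject == "young_01"), 1440)

  wd2 <- simulate_wearable(n_subjects_per_group = 4, days = 3,
                           bin_minutes = 60,
                           peak_hour = c(young = 14, old = 12),
                           noise_sd = 100, phase_jitter_sd = 0.3,
                           level_jitter_sd = 50, seed = 3)
  fits <- wd2 |>
    dplyr::group_by(subject, group) |>
    dplyr::group_modify(\(d, k) {
      f <- cosinor_fit(d$time_h, d$value)
      tibble::tibble(peak = f$peak_hour)
    }) |>
    dplyr::ungroup()
  expect_true(all(abs(fits$peak[fits$group == "young"] - 14) < 1.5))
  expect_true(all(abs(fits$peak[fits$group == "old"] - 12) < 1.5))
})
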
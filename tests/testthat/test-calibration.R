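test_that("delta notation is linear in the sample ratio and zero at the reference", {
  expect_equal(delta_from_ratios(0.0112, 0.0112), 0)
  expect_equal(delta_from_ratios(0.987, 1), -13)
  expect_equal(delta_from_ratios(0.973, 1), -27)
  # linearity in R_sa
  r <- seq(0.95, 1.05, by = 0.01)
  d <- delta_from_ratios(r, 1)
  expect_equal(diff(d), rep(10, length(r) - 1))
  expect_error(delta_from_ratios(-0.1, 1), "positive")
  expect_error(delta_from_ratios(0.9, 0), "positive")
})

test_that("multipoint OLS matches the normal-equations oracle and exact cases", {
  exact <- tibble::tibble(measured = c(-30, -25, -15), verified = measured)
  m <- fit_multipoint(exact)
  expect_equal(m$a, 1)
  expect_equal(m$b, 0, tolerance = 1e-12)

  shifted <- tibble::tibble(measured = c(-30, -25, -15) - 2,
                            verified = c(-30, -25, -15))
  m2 <- fit_multipoint(shifted)
  expect_equal(m2$a, 1)
  expect_equal(m2$b, 2, tolerance = 1e-12)

  withr::with_seed(42, {
    for (i in 1:5) {
      x <- runif(4, -38, -12)
      y <- x + rnorm(4, 0, 0.3)
      fit <- fit_multipoint(tibble::tibble(measured = x, verified = y))
      oracle <- ols_oracle(x, y)
      expect_equal(fit$a, unname(oracle["slope"]), tolerance = 1e-10)
      expect_equal(fit$b, unname(oracle["intercept"]), tolerance = 1e-10)
    }
  })
  expect_error(fit_multipoint(tibble::tibble(measured = c(-20, -20),
                                             verified = c(-20, -21))),
               "degenerate")
})

test_that("applying a calibration is the stated affine map", {
  m <- fit_multipoint(
    tibble::tibble(measured = c(-30, -10), verified = c(-30, -10))
  )
  expect_equal(apply_calibration(m, -26.39), -26.39)
  m$a <- 1; m$b <- 2
  expect_equal(apply_calibration(m, -28), -26)
  m$a <- 0.98; m$b <- -0.5
  expect_equal(apply_calibration(m, -20), -20.1)
  expect_error(apply_calibration(m, NA_real_), "finite")
})

test_that("two-point correction inverts affine distortions and matches multipoint on 2 anchors", {
  # unit slope, -1 permil offset
  m <- fit_two_point(tibble::tibble(measured = c(-29, -9),
                                    verified = c(-30, -10)))
  expect_equal(apply_calibration(m, -19), -20)

  # anchors measured exactly at verified values leave a reading unchanged
  anchors <- irms_standards("MASS") |>
    dplyr::filter(name %in% c("Glycine", "USGS 41")) |>
    dplyr::transmute(name, measured = verified_delta,
                     verified = verified_delta)
  ident <- fit_two_point(anchors)
  expect_equal(apply_calibration(ident, -29.20), -29.20)

  # random affine distortion of anchors + samples is undone exactly
  withr::with_seed(9, {
    for (i in 1:5) {
      a <- runif(1, 0.9, 1.1); b <- runif(1, -2, 2)
      known <- c(-31.2, -16.7)
      samples <- runif(10, -35, -12)
      m_i <- fit_two_point(tibble::tibble(measured = a * known + b,
                                          verified = known))
      expect_equal(apply_calibration(m_i, a * samples + b), samples,
                   tolerance = 1e-10)
    }
  })

  # same two standards: two-point and multipoint agree exactly
  std2 <- tibble::tibble(measured = c(-30.9, -16.4),
                         verified = c(-31.2, -16.72))
  mp <- fit_multipoint(std2)
  tp <- fit_two_point(std2)
  expect_equal(mp$a, tp$a, tolerance = 1e-12)
  expect_equal(mp$b, tp$b, tolerance = 1e-12)

  expect_error(fit_two_point(tibble::tibble(measured = c(-20, -20),
                                            verified = c(-31, -16))),
               "coincident")
})

test_that("calibration with positive slope preserves ordering", {
  withr::with_seed(13, {
    m <- fit_multipoint(tibble::tibble(measured = runif(5, -35, -10),
                                       verified = runif(5, -35, -10)))
    if (m$a < 0) m$a <- abs(m$a)
    x <- sort(runif(20, -40, -10))
    expect_true(all(diff(apply_calibration(m, x)) > 0))
  })
})

test_that("drift correction recovers an injected slope on noise-free runs", {
  specs <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                          true_delta = runif(100, -30, -12))
  cfg <- sim_config(noise_sd = 0, drift_per_position = 0.01, seed = 21)
  run <- simulate_irms_run(specs, "CSIRO", cfg)
  corrected <- drift_correct(run)
  expect_equal(attr(corrected, "drift_slope"), 0.01, tolerance = 1e-9)
  # corrected standards show no residual linear trend
  std <- dplyr::filter(corrected, sample_type == "standard",
                       standard_name == "USGS-40")
  resid_fit <- lm(raw_delta ~ sequence_no, data = std)
  expect_equal(unname(coef(resid_fit)[2]), 0, tolerance = 1e-9)

  # zero injected drift: output equals input
  cfg0 <- sim_config(noise_sd = 0, drift_per_position = 0, seed = 21)
  run0 <- simulate_irms_run(specs, "CSIRO", cfg0)
  out0 <- drift_correct(run0)
  expect_equal(out0$raw_delta, run0$raw_delta, tolerance = 1e-12)

  # a single standard block cannot constrain drift: identity + warning
  single <- standards_run(c(-26.39, -28.85), c(1L, 2L),
                          c("USGS-40", "High Organic Sediment Standard OAS"))
  expect_warning(out <- drift_correct(single), "unchanged")
  expect_equal(out$raw_delta, single$raw_delta)
})

test_that("run QC reports standard accuracy and replicate agreement", {
  std <- standards_run(c(-26.39, -26.39, -25.89), c(1L, 10L, 20L)) |>
    dplyr::mutate(delta_vpdb = raw_delta)
  qc <- run_qc(std)
  expect_equal(qc$max_abs_standard_deviation, 0.5)
  expect_equal(qc$n_replicate_pairs, 0L)
  expect_true(is.na(qc$replicate_mean_abs_diff))

  # replicate pairs: mean/sd of |difference|
  run <- dplyr::bind_rows(
    std,
    tibble::tibble(sequence_no = 30:32, sample_type = "unknown",
                   sample_id = c("A", "B", "C"),
                   standard_name = NA_character_,
                   raw_delta = c(-20, -25, -30), facility = "CSIRO",
                   delta_vpdb = raw_delta),
    tibble::tibble(sequence_no = 33:34, sample_type = "replicate",
                   sample_id = c("A", "B"), standard_name = NA_character_,
                   raw_delta = c(-20.2, -24.9), facility = "CSIRO",
                   delta_vpdb = raw_delta)
  )
  qc2 <- run_qc(run)
  expect_equal(qc2$n_replicate_pairs, 2L)
  expect_equal(qc2$replicate_mean_abs_diff, mean(c(0.2, 0.1)),
               tolerance = 1e-12)

  # extreme of |N(0, 0.1)| over 100 repeats lands in [0.2, 0.5]
  withr::with_seed(17, {
    noisy <- standards_run(-26.39 + rnorm(100, 0, 0.1), 1:100) |>
      dplyr::mutate(delta_vpdb = raw_delta)
    qc3 <- run_qc(noisy)
    expect_gte(qc3$max_abs_standard_deviation, 0.2)
    expect_lte(qc3$max_abs_standard_deviation, 0.5)
  })
})

test_that("calibrate_run reproduces verified standards on noise-free input and fills replicates", {
  specs <- tibble::tibble(sample_id = sprintf("S%03d", 1:60),
                          true_delta = runif(60, -30, -12))
  cfg <- sim_config(noise_sd = 0, drift_per_position = 0.02, seed = 31)
  for (method in c("multipoint", "two_point")) {
    run <- simulate_irms_run(specs, "MASS", cfg)
    cal <- calibrate_run(run, method)
    expect_equal(cal$qc$max_abs_standard_deviation, 0, tolerance = 1e-9)
    # corrected unknowns recover the simulated truth exactly
    truth <- attr(run, "truth") |>
      dplyr::filter(sample_type == "unknown") |>
      dplyr::arrange(sample_id)
    expect_equal(tidy(cal)$delta_vpdb, truth$true_delta, tolerance = 1e-9)
    expect_equal(cal$qc$n_replicate_pairs, 6L)
    expect_s3_class(glance(cal), "tbl_df")
  }
})
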
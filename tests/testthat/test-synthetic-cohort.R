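test_that("gain calibration solves the peak-change equation", {
  p <- lti_params(1, 2614, 758, 740)
  k <- calibrate_gain(p, rect_shape(1303), 58)
  expect_equal(k, 58 / (1 - exp(-1303 / 2614)), tolerance = 1e-12)
  expect_equal(round(k, 1), 147.8)
  k2 <- calibrate_gain(lti_params(1, 6573, 632, 740), rect_shape(1521), 90)
  expect_equal(round(k2, 1), 435.7, tolerance = 1e-3)
  # full equilibration: k tends to the target itself
  k3 <- calibrate_gain(lti_params(1, 10, 0, 740), rect_shape(1e4), 58)
  expect_equal(k3, 58, tolerance = 1e-9)
  expect_error(calibrate_gain(p, rect_shape(1303), -3), "positive")
})

test_that("trapezoidal calibration hits the target peak change", {
  for (vol in c(0.5, 1, 1.5)) {
    m <- ref_spleen(vol)
    target <- reference_change_targets()$T1_spleen[[as.character(vol)]]
    k <- calibrate_gain(m$params, m$shape, target)
    m$params$gain <- k
    achieved <- peak(m$params, m$shape)$y_peak - m$params$baseline
    expect_lt(abs(achieved - target), 1e-6 * target)
  }
})

test_that("noise-free generated series equal the closed form", {
  m <- ref_liver(0.5)
  s <- generate_t1_series(m$params, m$shape, t1_schedule(), 0, "T1_liver")
  expect_equal(s$values, rect_response(t1_schedule(), m$params, m$shape))
  expect_identical(s$marker, "T1_liver")
  # pre-onset samples sit at baseline
  expect_equal(s$values[s$times < 0], rep(740, 2))
})

test_that("generated noise is unbiased at a fixed time point", {
  m <- ref_liver(1)
  sched <- c(-300, 1800)
  set.seed(99)
  reps <- vapply(1:1000, function(i) {
    generate_t1_series(m$params, m$shape, sched, 5, "T1_liver")$values[2]
  }, numeric(1))
  truth <- rect_response(1800, m$params, m$shape)
  expect_lt(abs(mean(reps) - truth), 3 * 5 / sqrt(1000))
})

test_that("secondary markers follow the liver temporal shape and amplitudes", {
  cfg <- generator_config()
  cfg$noise_sd[] <- 0
  sched <- seq(-900, 3600, by = 900)
  # stiffness decreases by the configured amount on the noiseless curve
  # (dense grid: the 30-min clinical cadence undersamples the extremum)
  lsm <- generate_secondary_marker("LSM", 0.5, seq(-1800, 3600, 300), cfg)
  dev <- lsm$values - 2.6
  expect_lt(min(dev), 0)
  expect_equal(min(dev), -0.4, tolerance = 0.02)
  # proton-density fat fraction changes are tiny in absolute terms
  pdff <- generate_secondary_marker("PDFF", 1, sched, cfg)
  expect_lt(max(abs(pdff$values - 2)), 0.1)
  # zero amplitude gives a flat series
  flat <- generate_secondary_marker("T2star", 1, sched, cfg, amplitude = 1e-12)
  expect_equal(flat$values, rep(27, length(sched)), tolerance = 1e-9)
  expect_error(generate_secondary_marker("T1_liver", 1, sched, cfg))
})

test_that("cohort bookkeeping matches the study design", {
  co <- generate_cohort(6, c(0.5, 1, 1.5), generator_config(), seed = 42)
  expect_equal(nrow(co$covariates), 6)
  sessions <- dplyr::distinct(co$series, participant_id, session_volume_L)
  expect_equal(nrow(sessions), 18)
  expect_setequal(unique(co$series$marker), MARKER_IDS)
  n_t1 <- nrow(co$series[co$series$participant_id == "P01" &
                           co$series$session_volume_L == 0.5 &
                           co$series$marker == "T1_liver", ])
  expect_true(n_t1 >= 15 && n_t1 <= 17)
  # eligibility ranges
  expect_true(all(co$covariates$age >= 18 & co$covariates$age <= 60))
  expect_true(all(co$covariates$bmi >= 18.5 & co$covariates$bmi <= 30))
})

test_that("identical seed and config reproduce the cohort bit-for-bit", {
  a <- generate_cohort(3, c(0.5, 1.5), generator_config(), seed = 7)
  b <- generate_cohort(3, c(0.5, 1.5), generator_config(), seed = 7)
  expect_identical(a$series, b$series)
  expect_identical(a$covariates, b$covariates)
  c <- generate_cohort(3, c(0.5, 1.5), generator_config(), seed = 8)
  expect_false(identical(a$series$value, c$series$value))
})

test_that("zero jitter and zero noise reproduce the reference dynamics exactly", {
  cfg <- generator_config(jitter_sigma = 0, gain_cv = 0)
  cfg$noise_sd[] <- 0
  co <- generate_cohort(2, c(0.5, 1, 1.5), cfg, seed = 1)
  ref <- reference_dynamics()
  for (vol in c(0.5, 1, 1.5)) {
    tr <- co$truth[co$truth$session_volume_L == vol & co$truth$organ == "liver", ]
    expect_equal(tr$tau, rep(ref$liver[[as.character(vol)]]$tau, 2))
    expect_equal(tr$delta, rep(ref$liver[[as.character(vol)]]$delta, 2))
  }
  # calibration invariant: noiseless per-participant peak change equals the
  # configured target
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    if (tr$organ == "liver") {
      p <- lti_params(tr$gain, tr$tau, tr$delay, 740)
      achieved <- peak(p, rect_shape(tr$delta))$y_peak - 740
    } else {
      p <- lti_params(tr$gain, tr$tau, tr$delay, 1300)
      achieved <- peak(p, trapezoid_shape(tr$delta1, tr$delta2, tr$delta3))$y_peak - 1300
    }
    expect_lt(abs(achieved - tr$target_change), 1e-6 * tr$target_change)
  }
})

test_that("every generated series respects its marker's cadence", {
  co <- generate_cohort(2, c(1), generator_config(), seed = 2)
  steps <- co$series |>
    dplyr::group_by(marker) |>
    dplyr::summarise(step = min(diff(sort(unique(time_s)))))
  expect_equal(steps$step[steps$marker == "T1_liver"], 300)
  expect_equal(steps$step[steps$marker == "ADC"], 900)
  expect_equal(steps$step[steps$marker == "LSM"], 1800)
  # at least one pre-ingestion sample per marker
  pre <- co$series |>
    dplyr::group_by(marker) |>
    dplyr::summarise(n_pre = sum(time_s < 0))
  expect_true(all(pre$n_pre >= 1))
})

test_that("series round-trip through the cohort CSV format", {
  co <- generate_cohort(2, c(0.5), generator_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path, header = "# test artifact")
  back <- read_cohort_csv(path)
  expect_equal(nrow(back), nrow(co$series))
  s1 <- cohort_series(back, "P01", 0.5, "T1_spleen")
  s0 <- cohort_series(co, "P01", 0.5, "T1_spleen")
  expect_equal(s1$values, s0$values, tolerance = 1e-12)
})
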
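test_that("degenerate generator with zero variance and zero effects is constant", {
  d <- study_design(n_participants = 6, n_days = 2, n_weeks = 1)
  p <- generative_params(intercept = 100, kl_contrasts = c(0, 0, 0),
                         weight_coef = 0, contralateral_pain_coef = 0,
                         sd_patient = 0, sd_session_in_patient = 0,
                         sd_day_in_patient = 0, sd_rp = 0, sd_residual = 0,
                         machine_offsets = c(0, 0, 0))
  tab <- simulate_measurement_table(d, p, seed = 1)
  expect_true(all(tab$biomarker_value == 100))
  expect_true(all(tab$set %in% 1:2))
  expect_true(all(tab$kl_grade %in% 1:4))
})

test_that("generator is bit-reproducible under a fixed seed", {
  d <- study_design(n_participants = 10)
  expect_identical(simulate_measurement_table(d, seed = 7),
                   simulate_measurement_table(d, seed = 7))
  expect_false(identical(simulate_measurement_table(d, seed = 7)$biomarker_value,
                         simulate_measurement_table(d, seed = 8)$biomarker_value))
})

test_that("design and parameter validation rejects bad inputs", {
  expect_error(study_design(n_participants = 0), "positive")
  expect_error(generative_params(sd_patient = -1), "non-negative")
  expect_error(generative_params(quadrant_proportions = c(0.5, 0.5, 0.2, -0.2)),
               "quadrant_proportions")
  expect_error(generative_params(machine_offsets = c(5, 0, 0)), "reference")
})

test_that("patient-level variance of the generated table matches the generating SD", {
  ## direct variance decomposition by group means, no model fitting
  d <- study_design(n_participants = 400, n_days = 1, n_weeks = 1)
  p <- generative_params(kl_contrasts = c(0, 0, 0), weight_coef = 0,
                         contralateral_pain_coef = 0,
                         sd_patient = 82.06, sd_session_in_patient = 0,
                         sd_day_in_patient = 0, sd_rp = 0, sd_residual = 0,
                         machine_offsets = c(0, 0, 0))
  tab <- simulate_measurement_table(d, p, seed = 21)
  patient_means <- tapply(tab$biomarker_value, tab$participant, mean)
  expect_lt(abs(sd(patient_means) - 82.06) / 82.06, 0.10)
  ## rows of the same patient are identical when only the patient effect varies
  expect_true(all(tapply(tab$biomarker_value, tab$participant, sd) < 1e-10))
})

test_that("two sets of one session differ only by the residual", {
  d <- study_design(n_participants = 50, n_days = 1, n_weeks = 1)
  p <- generative_params(machine_offsets = c(0, 10, -10), sd_residual = 18.74)
  tab <- simulate_measurement_table(d, p, seed = 3)
  key <- paste(tab$participant, tab$session)
  set_diff <- tapply(seq_len(nrow(tab)), key, function(i) {
    diff(tab$biomarker_value[i][order(tab$set[i])])
  })
  ## between-set differences are N(0, 2 * sd_residual^2)
  expect_lt(abs(sd(unlist(set_diff)) - sqrt(2) * 18.74) / (sqrt(2) * 18.74), 0.2)
})

test_that("adjusted sample mean recovers the generating intercept", {
  d <- study_design(n_participants = 1000, n_days = 1, n_weeks = 1,
                    n_practitioners_day1 = 1)
  p <- generative_params(machine_offsets = c(0, 0, 0), sd_rp = 0)
  tab <- simulate_measurement_table(d, p, seed = 5)
  kl_dev <- drop(kl_contrast_matrix(4) %*% p$kl_contrasts)
  adj <- tab$biomarker_value - kl_dev[tab$kl_grade] -
    p$contralateral_pain_coef * tab$contralateral_pain -
    p$weight_coef * (tab$weight - mean(tab$weight))
  ## Monte-Carlo error ~ sd_patient / sqrt(n)
  expect_lt(abs(mean(adj) - 160.13), 4 * 82.06 / sqrt(1000))
})

test_that("angle trace hits the standing angle exactly at mid-cycle when noiseless", {
  tr <- simulate_angle_trace(1, cycle_duration = 6, sampling_rate = 100,
                             rest_duration = 2, noise_sd = 0, seed = 1)
  mid <- tr$angle[abs(tr$time - (2 + 3)) < 1e-9]
  expect_equal(mid, 0, tolerance = 1e-12)
  expect_equal(max(tr$angle), 90)
})

test_that("zero cycles gives a flat seated trace and no detected cycles", {
  tr <- simulate_angle_trace(0, noise_sd = 0, rest_duration = 3, seed = 1)
  expect_true(all(tr$angle == 90))
  kin <- smooth_and_differentiate(tr)
  expect_equal(nrow(detect_cycles(kin)), 0)
})

test_that("angle trace validation", {
  expect_error(simulate_angle_trace(1, noise_sd = -1), "noise_sd")
  expect_error(simulate_angle_trace(1, seated_angle = 0, standing_angle = 90),
               "seated_angle")
})

test_that("hit stream respects quadrant proportions", {
  tr <- simulate_angle_trace(5, noise_sd = 0, seed = 2)
  kin <- smooth_and_differentiate(tr)
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))
  iv <- quadrant_intervals(cyc)

  ## all mass in Q1 puts every onset inside a Q1 interval
  h1 <- simulate_hit_stream(cyc, 40, quadrant_proportions = c(1, 0, 0, 0), seed = 4)
  q1 <- iv[iv$quadrant == "Q1", ]
  inside_q1 <- vapply(h1$onset_time, function(t)
    any(t >= q1$t0 & t < q1$t1), logical(1))
  expect_true(all(inside_q1))
  expect_equal(nrow(h1), 40)

  ## multinomial allocation at the default skew
  h <- simulate_hit_stream(cyc, 1000, quadrant_proportions = c(0.4, 0.1, 0.1, 0.4),
                           seed = 5)
  counts <- table(factor(h$quadrant, paste0("Q", 1:4)))
  expected <- 1000 * c(0.4, 0.1, 0.1, 0.4)
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected * (1 - expected / 1000))))

  ## zero hits yield an empty, well-typed table
  h0 <- simulate_hit_stream(cyc, 0, seed = 6)
  expect_equal(nrow(h0), 0)
  expect_equal(number_of_hits(h0), 0)
  expect_error(simulate_hit_stream(cyc[0, ], 10, seed = 1), "no cycles")
})

test_that("hit amplitudes respect the threshold floor and ASL offset", {
  tr <- simulate_angle_trace(3, noise_sd = 0, seed = 2)
  kin <- smooth_and_differentiate(tr)
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))
  h <- simulate_hit_stream(cyc, 500, seed = 9)
  expect_true(all(h$peak_db >= 36))
  expect_true(all(h$peak_db <= 100))
  expect_true(all(h$asl_db <= h$peak_db - 5 + 1e-12))
  expect_true(all(h$peak_db - h$asl_db <= 15 + 1e-12))
})

test_that("waveform bursts peak at the requested amplitude", {
  h <- data.frame(onset_time = 0.005, peak_db = 60, asl_db = 50,
                  duration = 3e-4, quadrant = NA, cycle_index = NA)
  w <- simulate_waveform(h, sampling_rate = 1e5, noise_floor_db = 20, seed = 1)
  ## 60 dB re 1 uV is 1000 uV; noise perturbs the peak by well under 5%
  expect_lt(abs(max(abs(w$samples)) - 1000) / 1000, 0.05)
})

test_that("waveform round-trip recovers well-separated hits exactly", {
  h <- separated_hits(12, spacing = 0.01, peak_db = 60)
  w <- simulate_waveform(h, sampling_rate = 1e5, noise_floor_db = 20, seed = 2)
  det <- detect_hits(w)
  expect_equal(nrow(det), 12)
  expect_true(all(abs(det$onset_time - h$onset_time) <= 8e-4))

  w0 <- simulate_waveform(h[0, ], sampling_rate = 1e5, duration = 0.01,
                          noise_floor_db = 20, seed = 3)
  expect_equal(nrow(detect_hits(w0)), 0)
})

test_that("too-close bursts trigger the merge warning", {
  h <- data.frame(onset_time = c(0.005, 0.0054), peak_db = c(60, 60),
                  asl_db = 50, duration = 3e-4, quadrant = NA, cycle_index = NA)
  expect_warning(simulate_waveform(h, seed = 1), "merge")
})
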
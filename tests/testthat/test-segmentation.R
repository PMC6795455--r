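make_trace <- function(angle, fs = 100) {
  structure(data.frame(time = (seq_along(angle) - 1) / fs, angle = angle),
            sampling_rate = fs, class = c("angle_trace", "data.frame"))
}

test_that("a constant angle has zero velocity and acceleration", {
  kin <- smooth_and_differentiate(make_trace(rep(90, 500)))
  expect_lt(max(abs(kin$velocity)), 1e-8)
  expect_lt(max(abs(kin$acceleration)), 1e-6)
})

test_that("velocity of a noiseless raised-cosine cycle matches the analytic derivative", {
  fs <- 100; T <- 6
  t <- seq(0, T, by = 1 / fs)
  theta <- 45 + 45 * cos(2 * pi * t / T)
  ## pad with seated rests so filter edge effects stay clear of the cycle
  tr <- make_trace(c(rep(90, 200), theta, rep(90, 200)), fs)
  kin <- smooth_and_differentiate(tr, cutoff_hz = 2)
  inner <- 201:(200 + length(t))
  v_analytic <- -45 * (2 * pi / T) * sin(2 * pi * t / T)
  expect_lt(max(abs(kin$velocity[inner] - v_analytic)), 5)
  ## speed extrema at T/4 and 3T/4 within one sample
  i_peak <- inner[which.max(abs(kin$velocity[inner][t <= T / 2]))]
  expect_lt(abs(kin$time[i_peak] - (2 + T / 4)), 1.5 / fs + 1e-9)
})

test_that("velocity tracks the analytic derivative under goniometer noise", {
  tr <- simulate_angle_trace(3, cycle_duration = 6, noise_sd = 0.5, seed = 8)
  kin <- smooth_and_differentiate(tr)
  truth <- attr(tr, "truth")
  inside <- kin$time >= truth$start[1] & kin$time < truth$end[1]
  phase <- 2 * pi * (kin$time[inside] - truth$start[1]) / 6
  expect_lt(max(abs(kin$velocity[inside] - (-45 * (2 * pi / 6) * sin(phase)))), 5)
})

test_that("cutoff must respect Nyquist", {
  expect_error(smooth_and_differentiate(make_trace(rep(90, 100), fs = 3),
                                        cutoff_hz = 2), "Nyquist")
})

test_that("detect_cycles recovers simulated cycles", {
  tr <- simulate_angle_trace(5, noise_sd = 0, seed = 3)
  kin <- smooth_and_differentiate(tr)
  cyc <- detect_cycles(kin)
  truth <- attr(tr, "truth")
  expect_equal(nrow(cyc), 5)
  expect_true(all(abs(cyc$start - truth$start) <= 0.1))
  expect_true(all(abs(cyc$stand - truth$stand) <= 0.1))
  expect_true(all(abs(cyc$end - truth$end) <= 0.1))
  ## cycles are disjoint and ordered
  expect_true(all(cyc$end[-5] <= cyc$start[-1]))

  ## with realistic noise the count is still exact, boundaries a little looser
  trn <- simulate_angle_trace(5, noise_sd = 0.5, seed = 3)
  cycn <- detect_cycles(smooth_and_differentiate(trn))
  expect_equal(nrow(cycn), 5)
  expect_true(all(abs(cycn$stand - truth$stand) <= 0.3))
})

test_that("a half-movement is logged as incomplete, not returned as a cycle", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  descent <- 45 + 45 * cos(pi * t / 3) # seated to standing, never returns
  tr <- make_trace(c(rep(90, 300), descent, rep(0, 300)), fs)
  cyc <- detect_cycles(smooth_and_differentiate(tr))
  expect_equal(nrow(cyc), 0)
  expect_equal(attr(cyc, "incomplete"), 1L)
})

test_that("quadrant boundaries of a symmetric cycle sit at T/4 and 3T/4", {
  tr <- simulate_angle_trace(3, cycle_duration = 6, noise_sd = 0, seed = 1)
  kin <- smooth_and_differentiate(tr)
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))
  truth <- attr(tr, "truth")
  expect_true(all(abs(cyc$q2_start - (truth$start + 1.5)) <= 0.05))
  expect_true(all(abs(cyc$q4_start - (truth$start + 4.5)) <= 0.05))
})

test_that("asymmetric cycles split at the speed maximum of each half", {
  fs <- 100
  t_up <- seq(0, 4, by = 1 / fs)        # slow ascent, 4 s
  t_down <- seq(1 / fs, 2, by = 1 / fs) # fast descent, 2 s
  angle <- c(rep(90, 300),
             45 + 45 * cos(pi * t_up / 4),
             45 - 45 * cos(pi * t_down / 2),
             rep(90, 300))
  kin <- smooth_and_differentiate(make_trace(angle, fs))
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))
  expect_equal(nrow(cyc), 1)
  t0 <- 3 # rest length in seconds
  ## analytic speed maxima: mid-ascent (t0 + 2 s) and mid-descent (t0 + 5 s)
  expect_lt(abs(cyc$q2_start - (t0 + 2)), 0.1)
  expect_lt(abs(cyc$q4_start - (t0 + 5)), 0.1)
  ## brute-force argmax over raw samples agrees
  speed <- abs(kin$velocity)
  asc <- which(kin$time >= cyc$start & kin$time < cyc$stand)
  expect_equal(cyc$q2_start, kin$time[asc[which.max(speed[asc])]])
})

test_that("the four quadrant intervals tile each cycle exactly", {
  tr <- simulate_angle_trace(4, noise_sd = 0.3, seed = 5)
  kin <- smooth_and_differentiate(tr)
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))
  iv <- quadrant_intervals(cyc)
  for (ci in cyc$cycle_index) {
    v <- iv[iv$cycle_index == ci, ]
    expect_equal(v$t0[1], cyc$start[cyc$cycle_index == ci])
    expect_equal(v$t1[4], cyc$end[cyc$cycle_index == ci])
    expect_equal(v$t0[-1], v$t1[-4]) # contiguous, non-overlapping
  }
  ## Q2 ends exactly where Q3 begins (the stand time)
  expect_equal(iv$t1[iv$quadrant == "Q2"], cyc$stand)
  expect_equal(iv$t0[iv$quadrant == "Q3"], cyc$stand)
})

test_that("hit labelling uses half-open intervals and conserves counts", {
  tr <- simulate_angle_trace(3, noise_sd = 0, seed = 2)
  kin <- smooth_and_differentiate(tr)
  cyc <- quadrant_boundaries(kin, detect_cycles(kin))

  ## a hit exactly on the Q1/Q2 boundary belongs to Q2
  hb <- data.frame(onset_time = cyc$q2_start[1], peak_db = 50, asl_db = 40,
                   duration = 1e-4)
  expect_equal(assign_hits_to_quadrants(hb, cyc)$quadrant, "Q2")

  ## generator labels are reproduced exactly on the same segmentation
  h <- simulate_hit_stream(cyc, 200, seed = 7)
  relab <- assign_hits_to_quadrants(h[, c("onset_time", "peak_db", "asl_db", "duration")],
                                    cyc)
  expect_equal(relab$quadrant, h$quadrant)
  expect_equal(relab$cycle_index, h$cycle_index)

  ## conservation: quadrant counts plus off-cycle equals the total
  hoff <- rbind(h[, 1:4], data.frame(onset_time = c(0.1, max(kin$time) - 0.01),
                                     peak_db = 50, asl_db = 40, duration = 1e-4))
  lab <- assign_hits_to_quadrants(hoff, cyc)
  expect_equal(sum(!is.na(lab$quadrant)) + attr(lab, "off_cycle"), nrow(hoff))
  expect_equal(attr(lab, "off_cycle"), 2L)

  ## empty hit table stays empty but labelled
  e <- assign_hits_to_quadrants(h[0, 1:4], cyc)
  expect_equal(nrow(e), 0)
  expect_true(all(c("quadrant", "cycle_index") %in% names(e)))
})

test_that("segmentation is invariant to a constant angle offset", {
  tr <- simulate_angle_trace(3, noise_sd = 0.2, seed = 9)
  kin <- smooth_and_differentiate(tr)
  cyc <- detect_cycles(kin, seated_angle = 90, standing_angle = 0)
  tr2 <- tr
  tr2$angle <- tr$angle + 25
  kin2 <- smooth_and_differentiate(tr2)
  cyc2 <- detect_cycles(kin2, seated_angle = 115, standing_angle = 25)
  expect_equal(cyc$start, cyc2$start, tolerance = 1e-9)
  expect_equal(cyc$stand, cyc2$stand, tolerance = 1e-9)
  expect_equal(cyc$end, cyc2$end, tolerance = 1e-9)
})
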
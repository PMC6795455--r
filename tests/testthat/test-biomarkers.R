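# Shared segmentation fixture for profile tests
seg_fixture <- function(n_cycles = 3, seed = 2) {
  tr <- simulate_angle_trace(n_cycles, noise_sd = 0, seed = seed)
  kin <- smooth_and_differentiate(tr)
  quadrant_boundaries(kin, detect_cycles(kin))
}

test_that("number_of_hits counts onsets in scope", {
  h <- data.frame(onset_time = c(0.5, 1.5, 2.5), peak_db = 50, asl_db = 40,
                  duration = 1e-4)
  expect_equal(number_of_hits(h[0, ]), 0)
  expect_equal(number_of_hits(h), 3)
  expect_equal(number_of_hits(h, window = c(1, 2.5)), 1)
})

test_that("generator-configured hit totals are recovered", {
  cyc <- seg_fixture()
  h <- simulate_hit_stream(cyc, 120, seed = 3)
  expect_equal(number_of_hits(h), 120)
})

test_that("first vs repeat set scatter is tightly correlated at study-like variances", {
  ## the within-session repeatability pattern: between-knee variation dwarfs
  ## the residual, so set 1 vs set 2 hugs the diagonal
  d <- study_design(n_participants = 60, n_days = 1, n_weeks = 1,
                    n_practitioners_day1 = 1)
  p <- generative_params(machine_offsets = c(0, 0, 0))
  tab <- simulate_measurement_table(d, p, seed = 13)
  s1 <- tab$biomarker_value[tab$set == 1]
  s2 <- tab$biomarker_value[tab$set == 2]
  expect_gt(cor(s1, s2), 0.9)
})

test_that("feature profile puts identical hits in a single bin and conserves counts", {
  h <- data.frame(onset_time = rep(1, 10), peak_db = 55, asl_db = 45,
                  duration = 1e-4, quadrant = "Q1", cycle_index = 1L)
  prof <- feature_profile(h)
  expect_equal(sum(prof), 10)
  expect_equal(sum(prof > 0), 1)
  expect_equal(sum(prof["Q1", , ]), 10)

  cyc <- seg_fixture()
  hs <- simulate_hit_stream(cyc, 300, seed = 4)
  expect_equal(sum(feature_profile(hs)), 300) # all on-cycle by construction
})

test_that("out-of-range amplitudes are clamped into edge bins and logged", {
  h <- data.frame(onset_time = 1, peak_db = 120, asl_db = 10,
                  duration = 1e-4, quadrant = "Q2", cycle_index = 1L)
  prof <- feature_profile(h)
  expect_equal(sum(prof), 1)
  expect_equal(unname(prof["Q2", 1, 8]), 1) # lowest ASL bin, highest amplitude bin
  expect_equal(attr(prof, "clamped"), 1L)
})

test_that("profiles on a 1-D line give a first component explaining all variance", {
  cyc <- seg_fixture()
  base <- feature_profile(simulate_hit_stream(cyc, 50, seed = 5))
  profiles <- lapply(c(1, 2, 3, 4, 5), function(k) {
    p <- base
    p[] <- k * as.numeric(base)
    p
  })
  basis <- fit_pca_basis(profiles)
  expect_gt(basis$explained_var[1], 1 - 1e-10)
  expect_true(all(diff(basis$explained_var) <= 1e-12))
})

test_that("PCA loadings are orthonormal", {
  cyc <- seg_fixture()
  profiles <- lapply(1:6, function(s)
    feature_profile(simulate_hit_stream(cyc, 100 + 10 * s, seed = s)))
  basis <- fit_pca_basis(profiles)
  g <- crossprod(basis$loadings)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-10)
})

test_that("PC1 separates low- from high-amplitude developmental knees", {
  ## mirrors a developmental split: 5 clinically-mild, 3 clinically-severe
  cyc <- seg_fixture()
  mild <- lapply(1:5, function(s)
    feature_profile(simulate_hit_stream(
      cyc, 80, amplitude = list(mean_excess_db = 4, max_db = 100,
                                asl_offset_range_db = c(5, 15)), seed = s)))
  severe <- lapply(6:8, function(s)
    feature_profile(simulate_hit_stream(
      cyc, 250, amplitude = list(mean_excess_db = 25, max_db = 100,
                                 asl_offset_range_db = c(5, 15)), seed = s)))
  basis <- fit_pca_basis(c(mild, severe))
  pc1 <- basis$scores[, 1]
  expect_true(max(pc1[1:5]) < min(pc1[6:8]) || min(pc1[1:5]) > max(pc1[6:8]))
})

test_that("projection is consistent with fitting and with explicit arithmetic", {
  cyc <- seg_fixture()
  profiles <- lapply(1:6, function(s)
    feature_profile(simulate_hit_stream(cyc, 100 + 15 * s, seed = s)))
  basis <- fit_pca_basis(profiles)

  ## the mean profile scores at the origin
  meanp <- profiles[[1]]
  meanp[] <- Reduce(`+`, lapply(profiles, as.numeric)) / length(profiles)
  expect_lt(max(abs(project_candidates(meanp, basis))), 1e-8)

  ## a fitted profile reproduces its fit-time score
  expect_equal(unname(project_candidates(profiles[[2]], basis)),
               unname(basis$scores[2, ]), tolerance = 1e-10)

  ## independent arithmetic route: explicit centered dot product
  v <- as.numeric(profiles[[3]]) - basis$center
  manual <- vapply(1:3, function(j) sum(v * basis$loadings[, j]), numeric(1))
  expect_equal(unname(project_candidates(profiles[[3]], basis)), manual,
               tolerance = 1e-12)

  ## grid mismatch is refused
  other <- feature_profile(simulate_hit_stream(cyc, 50, seed = 9),
                           bin_config(n_bins = 4))
  expect_error(project_candidates(other, basis), "fingerprint")
})

test_that("PCA scores are order-invariant and scale linearly without normalization", {
  cyc <- seg_fixture()
  profiles <- lapply(1:6, function(s)
    feature_profile(simulate_hit_stream(cyc, 100 + 15 * s, seed = s)))
  b1 <- fit_pca_basis(profiles)
  b2 <- fit_pca_basis(rev(profiles))
  s1 <- project_candidates(profiles[[1]], b1)
  s2 <- project_candidates(profiles[[1]], b2)
  expect_equal(abs(unname(s1)), abs(unname(s2)), tolerance = 1e-8)

  doubled <- lapply(profiles, function(p) { p[] <- 2 * as.numeric(p); p })
  b3 <- fit_pca_basis(doubled)
  s3 <- project_candidates(doubled[[1]], b3)
  expect_equal(abs(unname(s3)), 2 * abs(unname(s1)), tolerance = 1e-8)
})

test_that("biomarker_set aggregates counts and conserves totals", {
  cyc <- seg_fixture()
  h <- simulate_hit_stream(cyc, 150, seed = 11)
  h <- rbind(h, data.frame(onset_time = 0.01, peak_db = 50, asl_db = 40,
                           duration = 1e-4, quadrant = NA, cycle_index = NA))
  bs <- biomarker_set(h)
  expect_equal(bs$n_hits, 151)
  expect_equal(bs$q1 + bs$q2 + bs$q3 + bs$q4 + bs$off_cycle, bs$n_hits)
})

test_that("quadrant distributions reflect the generating skew", {
  set.seed(20)
  n_sets <- 60
  mk <- function(props, kl) {
    counts <- t(vapply(seq_len(n_sets),
                       function(i) drop(rmultinom(1, 200, props)), numeric(4)))
    data.frame(q1 = counts[, 1], q2 = counts[, 2], q3 = counts[, 3],
               q4 = counts[, 4], kl_grade = kl)
  }
  qc <- rbind(mk(c(0.4, 0.1, 0.1, 0.4), 1), mk(c(0.4, 0.1, 0.1, 0.4), 3))
  qs <- quadrant_hit_distribution(qc)
  for (g in c("KL1", "KL2+")) {
    m <- setNames(qs$median[qs$group == g], qs$quadrant[qs$group == g])
    expect_gt(min(m["Q1"], m["Q4"]), max(m["Q2"], m["Q3"]))
  }

  ## zero hits everywhere: all summaries zero
  z <- quadrant_hit_distribution(data.frame(q1 = 0, q2 = 0, q3 = 0, q4 = 0,
                                            kl_grade = 2))
  expect_true(all(z$median == 0) && all(z$iqr_hi == 0))
})
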
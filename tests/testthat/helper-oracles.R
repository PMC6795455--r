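# Independent oracles used across the suite. Each reimplements the quantity
# under test by a different, direct route (literal state machine, closed-form
# ANOVA, analytic power), never by calling the code path it checks.

# Literal per-sample state machine for threshold-crossing hit detection:
# walks the rectified samples once, opening a hit at an above-threshold
# sample, closing it after gap_samples consecutive below-threshold samples,
# and refusing to open a new hit before the lockout after closure has passed.
oracle_detect <- function(w, threshold_db = 36, timing = hit_timing()) {
  x <- abs(w$samples)
  fs <- w$sampling_rate
  thr <- 10^(threshold_db / 20)
  gap_samples <- ceiling(timing$hit_definition_time * fs)
  lock_samples <- ceiling(timing$hit_lockout_time * fs)
  onsets <- integer(0)
  ends <- integer(0)
  state <- "idle"
  allowed_idx <- 1L
  open_at <- NA_integer_
  last_above <- NA_integer_
  for (i in seq_along(x)) {
    if (state == "idle") {
      if (x[i] >= thr && i >= allowed_idx) {
        state <- "open"
        open_at <- i
        last_above <- i
      }
    } else {
      if (x[i] >= thr) {
        last_above <- i
      } else if (i - last_above >= gap_samples) {
        onsets <- c(onsets, open_at)
        ends <- c(ends, last_above)
        allowed_idx <- last_above + gap_samples + lock_samples
        state <- "idle"
      }
    }
  }
  if (state == "open") {
    onsets <- c(onsets, open_at)
    ends <- c(ends, last_above)
  }
  data.frame(onset_time = (onsets - 1) / fs,
             peak_db = vapply(seq_along(onsets),
                              function(k) 20 * log10(max(x[onsets[k]:ends[k]])),
                              numeric(1)))
}

# Closed-form ANOVA (method-of-moments) variance components for a balanced
# two-level nested layout: patients / sessions-in-patient / sets. In the
# balanced interior case REML equals these estimators.
oracle_nested_anova <- function(value, patient, session) {
  patient <- as.character(patient)
  cell <- paste(patient, session)
  r <- length(value) / length(unique(cell))        # sets per session
  s <- length(unique(cell)) / length(unique(patient)) # sessions per patient
  grand <- mean(value)
  pat_mean <- tapply(value, patient, mean)
  cell_mean <- tapply(value, cell, mean)
  cell_pat <- tapply(patient, cell, function(p) p[1])
  a <- length(pat_mean)
  ms_pat <- r * s * sum((pat_mean - grand)^2) / (a - 1)
  ms_sess <- r * sum((cell_mean - pat_mean[cell_pat])^2) / (a * (s - 1))
  ms_err <- sum((value - cell_mean[cell])^2) / (length(value) - a * s)
  c(sd_patient = sqrt(max(0, (ms_pat - ms_sess) / (r * s))),
    sd_session = sqrt(max(0, (ms_sess - ms_err) / r)),
    sd_residual = sqrt(ms_err))
}

# Build a waveform object directly from a sample vector.
make_waveform <- function(samples, fs = 1e5) {
  structure(list(samples = samples, sampling_rate = fs,
                 start_time = 0, channel = "worst"),
            class = "waveform")
}

# Well-separated synthetic hit table for round-trip tests.
separated_hits <- function(k, spacing = 0.01, peak_db = 60) {
  data.frame(onset_time = spacing * seq_len(k), peak_db = peak_db,
             asl_db = peak_db - 10, duration = 3e-4,
             quadrant = NA_character_, cycle_index = NA_integer_)
}

# Random short test waveform: noise plus a random number of bursts at random
# times/amplitudes (possibly overlapping, to exercise merging and lockout).
random_waveform <- function(seed, fs = 1e5, dur = 0.02) {
  set.seed(seed)
  n <- ceiling(dur * fs)
  x <- rnorm(n, 0, 10^(20 / 20))
  k <- sample(0:6, 1)
  if (k > 0) {
    t0 <- sort(runif(k, 0, dur * 0.9))
    for (j in seq_len(k)) {
      amp <- 10^(runif(1, 40, 70) / 20)
      i0 <- floor(t0[j] * fs) + 1
      len <- sample(20:80, 1)
      idx <- i0:min(n, i0 + len - 1)
      x[idx] <- x[idx] + amp * exp(-(seq_along(idx) - 1) / 30) *
        sin(2 * pi * 0.2 * (seq_along(idx) - 1))
    }
  }
  make_waveform(x, fs)
}
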
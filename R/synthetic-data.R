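## Synthetic-data generator: emulates the repeated-measures AE study design
## (participants measured by several practitioners on day 1, then on repeated
## days/weeks, 2 recorded sets of 5 sit-stand-sit movements per session, one of
## 3 acquisition machines per participant) so that every downstream stage of
## the pipeline can be exercised and validated without clinical recordings.

#' Study design for the repeated-measures AE protocol
#'
#' Describes the factorial layout of the measurement study: how many
#' participants, measurement days and weeks, how many practitioners share day 1
#' (each applying the sensor for one session), how many recorded sets of
#' sit-stand-sit movements per session, and how many acquisition machines are
#' in use.
#'
#' On day 1 each participant is measured once by every practitioner (the
#' sensor is removed and re-applied between sessions, so day 1 carries
#' `n_practitioners_day1` sessions). On subsequent days a single session is
#' run by the participant's assigned home practitioner. Each participant uses
#' one machine for all of their sessions.
#'
#' @param n_participants number of participants.
#' @param n_days measurement days per week.
#' @param n_weeks number of measurement weeks.
#' @param n_practitioners_day1 practitioners who each run one day-1 session.
#' @param n_sets_per_session recorded sets of 5 movements per session.
#' @param n_movements_per_set sit-stand-sit movements per set.
#' @param n_machines number of acquisition machines.
#' @param machine_assignment optional integer vector (length `n_participants`)
#'   assigning each participant a machine in `1:n_machines`; if `NULL`,
#'   participants are randomized to machines when the table is simulated.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_participants = 45, n_days = 3, n_weeks = 3,
                         n_practitioners_day1 = 3, n_sets_per_session = 2,
                         n_movements_per_set = 5, n_machines = 3,
                         machine_assignment = NULL) {
  counts <- c(n_participants = n_participants, n_days = n_days,
              n_weeks = n_weeks, n_practitioners_day1 = n_practitioners_day1,
              n_sets_per_session = n_sets_per_session,
              n_movements_per_set = n_movements_per_set,
              n_machines = n_machines)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all design counts must be positive integers: ",
         paste(names(counts)[counts < 1 | counts != floor(counts)], collapse = ", "))
  if (!is.null(machine_assignment)) {
    if (length(machine_assignment) != n_participants)
      stop("machine_assignment must have one entry per participant")
    if (!all(machine_assignment %in% seq_len(n_machines)))
      stop("machine_assignment entries must be in 1:n_machines")
  }
  structure(as.list(c(counts, list(machine_assignment = machine_assignment))),
            names = c(names(counts), "machine_assignment"),
            class = "study_design")
}

#' Generative parameters for the measurement-table simulator
#'
#' Collects the fixed-effect coefficients, random-effect standard deviations
#' and hit-stream parameters used to simulate biomarker measurement tables.
#' Defaults are the point estimates reported for the "number of hits"
#' biomarker: the association-model fixed effects (intercept 160.13 hits,
#' successive-difference KL contrasts, 2.06 hits/kg for weight, 57.05 hits for
#' contralateral knee pain) and the day-one reproducibility variance
#' components (patient 82.06, session-in-patient 46.02, practitioner 6.05,
#' residual 18.74 hits).
#'
#' @param intercept grand-mean number of hits (across KL grades, at mean
#'   weight, no contralateral pain).
#' @param kl_contrasts length-3 numeric, successive-difference KL effects
#'   (KL1 vs KL2, KL2 vs KL3, KL3 vs KL4), each `level_i - level_{i+1}`.
#' @param weight_coef hits per kg of body weight (weight is centered at the
#'   sample mean before the coefficient is applied).
#' @param contralateral_pain_coef hits added when the contralateral knee hurts.
#' @param sd_patient,sd_session_in_patient,sd_day_in_patient,sd_rp,sd_residual
#'   random-effect standard deviations (hits). Set a component to 0 to switch
#'   it off; session effects are shared by the sets of one session, day
#'   effects by the sessions of one day.
#' @param machine_offsets per-machine fixed offsets (hits); the first machine
#'   is the reference and must be 0.
#' @param quadrant_proportions length-4 non-negative fractions summing to 1:
#'   expected share of hits in movement quadrants Q1..Q4. The default is
#'   skewed to Q1 and Q4 (ascending-acceleration / descending-deceleration),
#'   where hit counts are consistently highest.
#' @param amplitude list describing the per-hit amplitude law:
#'   `mean_excess_db` (exponential mean above the detection threshold),
#'   `max_db` (truncation), `asl_offset_range_db` (uniform range of the
#'   positive peak-minus-ASL offset).
#' @param kl_probs sampling probabilities for KL grades 1..4 (default mirrors
#'   the cohort mix 12:22:27:7).
#' @return an object of class `generative_params`.
#' @export
generative_params <- function(intercept = 160.13,
                              kl_contrasts = c(-81.77, 22.54, 38.39),
                              weight_coef = 2.06,
                              contralateral_pain_coef = 57.05,
                              sd_patient = 82.06,
                              sd_session_in_patient = 46.02,
                              sd_day_in_patient = 0,
                              sd_rp = 6.05,
                              sd_residual = 18.74,
                              machine_offsets = c(0, 0, 0),
                              quadrant_proportions = c(0.4, 0.1, 0.1, 0.4),
                              amplitude = list(mean_excess_db = 8,
                                               max_db = 100,
                                               asl_offset_range_db = c(5, 15)),
                              kl_probs = c(12, 22, 27, 7) / 68) {
  sds <- c(sd_patient = sd_patient,
           sd_session_in_patient = sd_session_in_patient,
           sd_day_in_patient = sd_day_in_patient,
           sd_rp = sd_rp, sd_residual = sd_residual)
  if (any(sds < 0))
    stop("random-effect SDs must be non-negative: ",
         paste(names(sds)[sds < 0], collapse = ", "))
  if (length(kl_contrasts) != 3) stop("kl_contrasts must have length 3")
  if (machine_offsets[1] != 0) stop("the reference machine offset must be 0")
  if (length(quadrant_proportions) != 4 || any(quadrant_proportions < 0) ||
      abs(sum(quadrant_proportions) - 1) > 1e-12)
    stop("quadrant_proportions must be 4 non-negative fractions summing to 1")
  if (abs(sum(kl_probs) - 1) > 1e-8) kl_probs <- kl_probs / sum(kl_probs)
  structure(list(intercept = intercept, kl_contrasts = kl_contrasts,
                 weight_coef = weight_coef,
                 contralateral_pain_coef = contralateral_pain_coef,
                 sd_patient = sd_patient,
                 sd_session_in_patient = sd_session_in_patient,
                 sd_day_in_patient = sd_day_in_patient,
                 sd_rp = sd_rp, sd_residual = sd_residual,
                 machine_offsets = machine_offsets,
                 quadrant_proportions = quadrant_proportions,
                 amplitude = amplitude, kl_probs = kl_probs),
            class = "generative_params")
}

#' Successive-difference contrast matrix for KL grades
#'
#' Contrast coding in which coefficient `i` estimates `level_i - level_{i+1}`
#' (so "KL 1 vs KL 2" is the mean of KL1 minus the mean of KL2) and the model
#' intercept is the unweighted average over the KL levels. This is the coding
#' under which the association-model intercept reads as "average number of
#' hits across all KL scores".
#'
#' @param k number of ordinal levels (default 4, KL grades 1-4).
#' @return a k x (k-1) contrast matrix.
#' @export
kl_contrast_matrix <- function(k = 4) {
  cm <- -MASS::contr.sdif(k)
  colnames(cm) <- paste0(seq_len(k - 1), "vs", seq_len(k - 1) + 1)
  cm
}

## Internal: per-level KL deviations (mean 0 over levels) implied by the
## successive-difference coefficients.
kl_level_effects <- function(kl_contrasts) {
  drop(kl_contrast_matrix(length(kl_contrasts) + 1) %*% kl_contrasts)
}

#' Simulate a biomarker measurement table
#'
#' Draws one row per participant x day x session x set from the Gaussian
#' mixed model underlying both reproducibility models and the association
#' model: fixed effects for KL grade (successive-difference coding), centered
#' body weight, contralateral knee pain and machine, plus independent Gaussian
#' random effects for participant, day-within-participant,
#' session-within-participant and practitioner, and a residual per set. Rows
#' sharing a grouping unit share the realized random effect, so the two sets
#' of one session differ only in the residual.
#'
#' The response is continuous (Gaussian), matching the Gaussian linear mixed
#' models fitted downstream; `response = "count"` rounds and clips at zero
#' for realism at the cost of exact parameter recovery.
#'
#' @param design a [study_design()].
#' @param params a [generative_params()].
#' @param seed integer seed; fixing it makes the table bit-reproducible.
#' @param response `"gaussian"` (default) or `"count"`.
#' @return a data.frame with one `MeasurementRecord` per row: design labels
#'   (`participant`, `week`, `day`, `day_index`, `session`, `set`,
#'   `practitioner`, `machine`), covariates (`kl_grade`, `weight`,
#'   `contralateral_pain`, `age`, `sex`, `bmi`, `womac_pain`,
#'   `womac_stiffness`, `womac_function`, `vas_pain_worst_knee`) and
#'   `biomarker_name`, `biomarker_value`.
#' @export
simulate_measurement_table <- function(design = study_design(),
                                       params = generative_params(),
                                       seed = 1L,
                                       response = c("gaussian", "count")) {
  stopifnot(inherits(design, "study_design"), inherits(params, "generative_params"))
  response <- match.arg(response)
  set.seed(as.integer(seed))

  np <- design$n_participants
  n_rp <- design$n_practitioners_day1
  days_total <- design$n_days * design$n_weeks

  machine <- design$machine_assignment
  if (is.null(machine)) machine <- sample.int(design$n_machines, np, replace = TRUE)
  home_rp <- sample.int(n_rp, np, replace = TRUE)

  ## participant-level covariates (ranges mimic a mid/late-life OA cohort)
  kl_grade <- sample.int(4, np, replace = TRUE, prob = params$kl_probs)
  weight <- rnorm(np, 82, 16)
  pain <- rbinom(np, 1, 0.5)
  age <- round(rnorm(np, 62, 9))
  sex <- sample(c("F", "M"), np, replace = TRUE)
  bmi <- rnorm(np, 29, 4.5)
  womac_pain <- pmax(0, pmin(50, round(rnorm(np, 17, 11))))
  womac_stiffness <- pmax(0, pmin(20, round(rnorm(np, 9, 5))))
  womac_function <- pmax(0, pmin(170, round(rnorm(np, 58, 38))))
  vas <- pmax(0, pmin(100, round(rnorm(np, 45, 20))))

  u_patient <- rnorm(np, 0, params$sd_patient)
  u_rp <- rnorm(n_rp, 0, params$sd_rp)

  ## enumerate the design grid: day 1 carries one session per practitioner,
  ## later days one session by the home practitioner
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    grid <- do.call(rbind, lapply(seq_len(days_total), function(d) {
      n_sess <- if (d == 1L) n_rp else 1L
      expand.grid(session = seq_len(n_sess),
                  set = seq_len(design$n_sets_per_session),
                  day_index = d)
    }))
    grid$participant <- p
    rows[[p]] <- grid
  }
  tab <- do.call(rbind, rows)
  tab$week <- (tab$day_index - 1L) %/% design$n_days + 1L
  tab$day <- (tab$day_index - 1L) %% design$n_days + 1L
  tab$practitioner <- ifelse(tab$day_index == 1L, tab$session, home_rp[tab$participant])
  tab$machine <- machine[tab$participant]

  ## realized random effects, shared within their grouping unit
  day_key <- paste(tab$participant, tab$day_index)
  sess_key <- paste(day_key, tab$session)
  u_day <- rnorm(length(unique(day_key)), 0, params$sd_day_in_patient)
  names(u_day) <- unique(day_key)
  u_sess <- rnorm(length(unique(sess_key)), 0, params$sd_session_in_patient)
  names(u_sess) <- unique(sess_key)

  kl_dev <- kl_level_effects(params$kl_contrasts)
  weight_c <- weight - mean(weight)
  mu <- params$intercept +
    kl_dev[kl_grade[tab$participant]] +
    params$weight_coef * weight_c[tab$participant] +
    params$contralateral_pain_coef * pain[tab$participant] +
    params$machine_offsets[tab$machine] +
    u_patient[tab$participant] +
    u_day[day_key] + u_sess[sess_key] + u_rp[tab$practitioner]
  value <- mu + rnorm(nrow(tab), 0, params$sd_residual)
  if (response == "count") value <- pmax(0, round(value))

  out <- data.frame(
    participant = tab$participant, week = tab$week, day = tab$day,
    day_index = tab$day_index, session = tab$session, set = tab$set,
    practitioner = tab$practitioner, machine = tab$machine,
    kl_grade = kl_grade[tab$participant],
    weight = weight[tab$participant],
    contralateral_pain = pain[tab$participant],
    age = age[tab$participant], sex = sex[tab$participant],
    bmi = bmi[tab$participant],
    womac_pain = womac_pain[tab$participant],
    womac_stiffness = womac_stiffness[tab$participant],
    womac_function = womac_function[tab$participant],
    vas_pain_worst_knee = vas[tab$participant],
    biomarker_name = "number_of_hits",
    biomarker_value = as.numeric(value),
    stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$day_index, out$session, out$set), ]
  rownames(out) <- NULL
  out
}

#' Simulate a goniometer knee-angle trace
#'
#' Generates a time-stamped knee-flexion trace containing `n_cycles` smooth
#' sit-stand-sit excursions. Convention: flexion is positive, seated is about
#' 90 degrees, standing about 0; "ascending" (standing up) therefore means a
#' decreasing angle. Each excursion follows a raised-cosine profile of length
#' `cycle_duration`, flanked by seated rests of length `rest_duration`, with
#' additive Gaussian sensor noise.
#'
#' @param n_cycles number of sit-stand-sit movements (0 gives a flat seated
#'   trace).
#' @param cycle_duration seconds per full sit-stand-sit excursion.
#' @param sampling_rate goniometer sampling rate, Hz.
#' @param seated_angle,standing_angle degrees of knee flexion; seated must
#'   exceed standing.
#' @param rest_duration seconds of seated rest before, between and after
#'   cycles.
#' @param noise_sd additive Gaussian noise SD, degrees (must be >= 0).
#' @param seed integer seed.
#' @return a data.frame of class `angle_trace` with columns `time` and
#'   `angle`; attributes `sampling_rate` and `truth` (a data.frame of the
#'   generated cycle start/stand/end times, for validation).
#' @export
simulate_angle_trace <- function(n_cycles, cycle_duration = 6,
                                 sampling_rate = 100,
                                 seated_angle = 90, standing_angle = 0,
                                 rest_duration = 2, noise_sd = 0.5,
                                 seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (seated_angle <= standing_angle) stop("seated_angle must exceed standing_angle")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_cycles < 0 || n_cycles != floor(n_cycles)) stop("n_cycles must be a non-negative integer")
  set.seed(as.integer(seed))

  total <- rest_duration * (n_cycles + 1) + n_cycles * cycle_duration
  if (n_cycles == 0) total <- max(rest_duration, 1 / sampling_rate)
  time <- seq(0, total, by = 1 / sampling_rate)
  angle <- rep(seated_angle, length(time))
  truth <- data.frame(cycle_index = integer(0), start = numeric(0),
                      stand = numeric(0), end = numeric(0))
  amp <- (seated_angle - standing_angle) / 2
  mid <- (seated_angle + standing_angle) / 2
  for (k in seq_len(n_cycles)) {
    t0 <- rest_duration * k + cycle_duration * (k - 1)
    inside <- time >= t0 & time < t0 + cycle_duration
    ## raised cosine: seated at the ends, standing at mid-cycle
    angle[inside] <- mid + amp * cos(2 * pi * (time[inside] - t0) / cycle_duration)
    truth <- rbind(truth, data.frame(cycle_index = k, start = t0,
                                     stand = t0 + cycle_duration / 2,
                                     end = t0 + cycle_duration))
  }
  if (noise_sd > 0) angle <- angle + rnorm(length(angle), 0, noise_sd)
  structure(data.frame(time = time, angle = angle),
            sampling_rate = sampling_rate, truth = truth,
            class = c("angle_trace", "data.frame"))
}

#' Simulate a stream of AE hits across movement quadrants
#'
#' Allocates `total_hits` onset times to the four movement quadrants of the
#' supplied cycles by a multinomial draw with the given proportions, placing
#' each hit uniformly within its quadrant's time intervals (intervals of the
#' same quadrant are chosen with probability proportional to their length).
#' Peak amplitudes follow `threshold + Exponential(mean_excess_db)` truncated
#' at `max_db`; the average signal level sits a uniform 5-15 dB (by default)
#' below the peak.
#'
#' @param cycles segmented cycles with quadrant boundaries, as returned by
#'   [quadrant_boundaries()] (or the `truth`-style data.frame produced by the
#'   generator plus boundaries).
#' @param total_hits number of hits to place.
#' @param quadrant_proportions length-4 fractions summing to 1.
#' @param amplitude amplitude-law parameters, see [generative_params()].
#' @param threshold_db detection threshold floor for peak amplitudes.
#' @param seed integer seed.
#' @return a data.frame of hits: `onset_time`, `peak_db`, `asl_db`,
#'   `duration`, plus the generating `quadrant` and `cycle_index` labels.
#' @export
simulate_hit_stream <- function(cycles, total_hits,
                                quadrant_proportions = c(0.4, 0.1, 0.1, 0.4),
                                amplitude = list(mean_excess_db = 8,
                                                 max_db = 100,
                                                 asl_offset_range_db = c(5, 15)),
                                threshold_db = 36, seed = 1L) {
  if (abs(sum(quadrant_proportions) - 1) > 1e-12 || any(quadrant_proportions < 0))
    stop("quadrant_proportions must be non-negative and sum to 1")
  if (total_hits < 0) stop("total_hits must be non-negative")
  empty <- data.frame(onset_time = numeric(0), peak_db = numeric(0),
                      asl_db = numeric(0), duration = numeric(0),
                      quadrant = character(0), cycle_index = integer(0),
                      stringsAsFactors = FALSE)
  if (total_hits == 0) return(empty)
  iv <- quadrant_intervals(cycles)
  if (nrow(iv) == 0) stop("cannot place hits: no cycles supplied")
  set.seed(as.integer(seed))

  nq <- drop(rmultinom(1, total_hits, quadrant_proportions))
  out <- vector("list", 4)
  for (q in 1:4) {
    if (nq[q] == 0) next
    qiv <- iv[iv$quadrant == paste0("Q", q), , drop = FALSE]
    len <- qiv$t1 - qiv$t0
    pick <- sample.int(nrow(qiv), nq[q], replace = TRUE, prob = len)
    onset <- qiv$t0[pick] + runif(nq[q]) * len[pick]
    out[[q]] <- data.frame(onset_time = onset, quadrant = paste0("Q", q),
                           cycle_index = qiv$cycle_index[pick],
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  n <- nrow(hits)
  peak <- threshold_db + rexp(n, 1 / amplitude$mean_excess_db)
  peak <- pmin(peak, amplitude$max_db)
  off <- runif(n, amplitude$asl_offset_range_db[1], amplitude$asl_offset_range_db[2])
  hits$peak_db <- peak
  hits$asl_db <- peak - off
  hits$duration <- runif(n, 2e-4, 1.5e-3)
  hits <- hits[order(hits$onset_time),
               c("onset_time", "peak_db", "asl_db", "duration", "quadrant", "cycle_index")]
  rownames(hits) <- NULL
  hits
}

#' Synthesize an AE waveform from a table of hits
#'
#' Raw-signal stand-in for the acquisition hardware: embeds one decaying
#' sinusoid burst per hit, scaled so the burst's peak rectified sample equals
#' the hit's peak amplitude (10^(dB/20) microvolts), in Gaussian noise whose
#' RMS sits at `noise_floor_db`. Lets the hit detector be tested end-to-end
#' against known ground truth.
#'
#' @param hits data.frame with at least `onset_time` and `peak_db`.
#' @param sampling_rate waveform sampling rate, Hz.
#' @param duration total waveform length, s (default covers the last hit).
#' @param burst list: `freq_hz` (carrier), `decay_s` (exponential envelope
#'   time constant).
#' @param noise_floor_db Gaussian noise RMS in dB re 1 microvolt; must sit
#'   below the detection threshold the waveform is meant to be analyzed at.
#' @param threshold_db threshold the margin is checked against.
#' @param min_gap bursts closer together than this (s) trigger a warning:
#'   they will merge into one detected hit.
#' @param seed integer seed.
#' @return an object of class `waveform`: list with `samples` (microvolts),
#'   `sampling_rate`, `start_time`, `channel`.
#' @export
simulate_waveform <- function(hits, sampling_rate = 1e5, duration = NULL,
                              burst = list(freq_hz = 2e4, decay_s = 3e-4),
                              noise_floor_db = 20, threshold_db = 36,
                              min_gap = 8e-4, seed = 1L) {
  if (noise_floor_db >= threshold_db - 6)
    stop("noise_floor_db must sit at least 6 dB below the detection threshold")
  set.seed(as.integer(seed))
  if (is.null(duration))
    duration <- if (nrow(hits)) max(hits$onset_time) + 0.01 else 0.01
  n <- max(2L, ceiling(duration * sampling_rate))
  x <- rnorm(n, 0, db_to_volts(noise_floor_db))
  if (nrow(hits) >= 2) {
    gaps <- diff(sort(hits$onset_time))
    if (any(gaps < min_gap))
      warning(sum(gaps < min_gap),
              " burst pair(s) closer than the hit-definition gap; they will merge in detection")
  }
  dt <- 1 / sampling_rate
  blen <- max(8L, ceiling(6 * burst$decay_s / dt))
  tb <- (seq_len(blen) - 1) * dt
  shape <- exp(-tb / burst$decay_s) * sin(2 * pi * burst$freq_hz * tb)
  shape <- shape / max(abs(shape))
  for (i in seq_len(nrow(hits))) {
    i0 <- floor(hits$onset_time[i] * sampling_rate) + 1L
    idx <- i0:min(n, i0 + blen - 1L)
    if (length(idx) < 1 || i0 > n) next
    x[idx] <- x[idx] + db_to_volts(hits$peak_db[i]) * shape[seq_along(idx)]
  }
  structure(list(samples = x, sampling_rate = sampling_rate,
                 start_time = 0, channel = "worst"),
            class = "waveform")
}
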
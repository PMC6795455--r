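## Pipeline interface: validated CSV I/O, run configuration, and a
## one-command synthetic study that exercises every stage end to end
## (simulate -> detect -> segment -> biomarkers -> reproducibility models ->
## association model -> quadrant summary -> power), with seed and
## configuration-hash provenance stamped on the outputs.

#' Run configuration for the end-to-end synthetic study
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param design a [study_design()].
#' @param params a [generative_params()].
#' @param threshold_db acquisition/detection threshold (dB re 1 microvolt).
#' @param frequency_config acquisition frequency-range label; metadata only
#'   (the software applies no band-pass filtering).
#' @param timing a [hit_timing()].
#' @param cutoff_hz angle-trace low-pass cutoff for segmentation.
#' @param bins a [bin_config()] for feature profiles.
#' @param n_developmental number of synthetic developmental knees used to
#'   fit the frozen PCA basis.
#' @param candidate_pool covariates offered to forward selection.
#' @param power_effect,power_alpha,power_replicates trial-power settings.
#' @param out_dir optional directory; when set, [run_full_study()] writes its
#'   CSV outputs there.
#' @return an object of class `run_config` carrying a `config_hash`.
#' @export
run_config <- function(seed = 1L,
                       design = study_design(),
                       params = generative_params(),
                       threshold_db = 36,
                       frequency_config = c("wide_20_400kHz", "narrow_20_80kHz"),
                       timing = hit_timing(),
                       cutoff_hz = 2,
                       bins = bin_config(),
                       n_developmental = 8,
                       candidate_pool = c("kl_grade", "weight",
                                          "contralateral_pain", "age", "bmi"),
                       power_effect = 0.5, power_alpha = 0.05,
                       power_replicates = 400,
                       out_dir = NULL) {
  frequency_config <- match.arg(frequency_config)
  cfg <- list(seed = as.integer(seed), design = design, params = params,
              threshold_db = threshold_db, frequency_config = frequency_config,
              timing = timing, cutoff_hz = cutoff_hz, bins = bins,
              n_developmental = n_developmental,
              candidate_pool = candidate_pool,
              power_effect = power_effect, power_alpha = power_alpha,
              power_replicates = power_replicates, out_dir = out_dir)
  cfg$config_hash <- fnv1a_hash(paste(deparse(cfg), collapse = ""))
  structure(cfg, class = "run_config")
}

#' Write / read a measurement table as CSV
#'
#' One row per participant x day x session x set with the documented header
#' (see [simulate_measurement_table()] for the columns).
#'
#' @param table a measurement table.
#' @param path file path.
#' @export
write_measurement_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Validate a measurement CSV
#'
#' Schema check (required columns, numeric types, label ranges), duplicate
#' detection over the design key, and a completeness report giving
#' complete-case counts per covariate — the basis of complete-case model
#' fitting.
#'
#' @param path path to a measurement CSV.
#' @return list: `table` (the parsed data.frame), `errors` (character,
#'   empty when valid), `valid`, `report` (list with `n_rows`,
#'   `n_participants`, `complete_by_covariate`, `n_complete_participants`,
#'   `n_duplicate_rows`).
#' @export
validate_measurement_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  errors <- character(0)
  required <- c("participant", "day_index", "session", "set", "practitioner",
                "machine", "kl_grade", "weight", "contralateral_pain",
                "biomarker_name", "biomarker_value")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    errors <- c(errors, paste("missing required column(s):",
                              paste(miss, collapse = ", ")))
  if ("biomarker_value" %in% names(tab)) {
    if (!is.numeric(tab$biomarker_value))
      errors <- c(errors, "biomarker_value is not numeric")
    else if (any(!is.finite(tab$biomarker_value)))
      errors <- c(errors, "biomarker_value contains non-finite entries")
  }
  if ("set" %in% names(tab) && !all(tab$set %in% c(1, 2)))
    errors <- c(errors, "set index must be 1 or 2")
  if ("kl_grade" %in% names(tab) &&
      !all(is.na(tab$kl_grade) | tab$kl_grade %in% 1:4))
    errors <- c(errors, "kl_grade must lie in 1..4")
  n_dup <- 0L
  key_cols <- intersect(c("participant", "day_index", "session", "set",
                          "biomarker_name"), names(tab))
  if (length(key_cols) >= 4) {
    key <- do.call(paste, tab[key_cols])
    n_dup <- sum(duplicated(key))
    if (n_dup > 0) errors <- c(errors, paste(n_dup, "duplicate design row(s)"))
  }
  covariates <- intersect(c("kl_grade", "weight", "contralateral_pain", "age",
                            "sex", "bmi", "womac_pain", "womac_stiffness",
                            "womac_function", "vas_pain_worst_knee"),
                          names(tab))
  complete_by_cov <- vapply(covariates, function(v) sum(!is.na(tab[[v]])),
                            numeric(1))
  n_complete_participants <- if ("participant" %in% names(tab) && length(covariates)) {
    ok <- complete.cases(tab[covariates])
    length(unique(tab$participant[stats::ave(ok, tab$participant, FUN = all) > 0]))
  } else NA_integer_
  list(table = tab, errors = errors, valid = length(errors) == 0,
       report = list(n_rows = nrow(tab),
                     n_participants = if ("participant" %in% names(tab))
                       length(unique(tab$participant)) else NA_integer_,
                     complete_by_covariate = complete_by_cov,
                     n_complete_participants = n_complete_participants,
                     n_duplicate_rows = n_dup))
}

#' Write a raw signal as CSV with a YAML sidecar
#'
#' Two-column CSV (`time_s`, `value`) plus a small YAML file recording the
#' sampling rate, units, knee and channel.
#'
#' @param time,value numeric vectors.
#' @param path CSV path; the sidecar is written to `paste0(path, ".yaml")`.
#' @param sampling_rate Hz.
#' @param units,knee,channel metadata strings.
#' @export
write_signal_csv <- function(time, value, path, sampling_rate,
                             units = "uV", knee = "worst", channel = "ae") {
  write.csv(data.frame(time_s = time, value = value), path, row.names = FALSE)
  yaml::write_yaml(list(sampling_rate_hz = sampling_rate, units = units,
                        knee = knee, channel = channel),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Run the full synthetic study
#'
#' One-command pipeline over a [run_config()]:
#' \enumerate{
#'   \item simulate the measurement table under the configured design;
#'   \item simulate one session's raw signals (angle trace and AE waveform),
#'     detect hits, segment cycles into quadrants and label the hits, with a
#'     conservation audit of hit counts across stages;
#'   \item build developmental feature profiles, fit and freeze the PCA
#'     basis, and score an evaluation profile;
#'   \item fit the day-one and longitudinal reproducibility models;
#'   \item run forward selection and the final REML association model;
#'   \item summarize per-quadrant hit counts by KL group;
#'   \item simulate trial power from the fitted association components.
#' }
#' Every output carries the seed and configuration hash; reruns with the
#' same config are identical.
#'
#' @param config a [run_config()].
#' @return a report bundle (list) with elements `measurements`, `signals`,
#'   `detection_audit`, `pca`, `reliability_day1`, `reliability_longitudinal`,
#'   `association`, `quadrant_summary`, `power`, `provenance`.
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 12)

  ## 1. measurement table
  tab <- simulate_measurement_table(config$design, config$params, seed = seeds[1])

  ## 2. one session of raw signals, end to end
  n_mov <- config$design$n_movements_per_set
  trace <- simulate_angle_trace(n_mov, seed = seeds[2])
  kin <- smooth_and_differentiate(trace, cutoff_hz = config$cutoff_hz)
  cycles <- quadrant_boundaries(kin, detect_cycles(kin))
  truth_hits <- simulate_hit_stream(cycles, total_hits = 120,
                                    quadrant_proportions = config$params$quadrant_proportions,
                                    amplitude = config$params$amplitude,
                                    threshold_db = config$threshold_db,
                                    seed = seeds[3])
  wav <- simulate_waveform(truth_hits, sampling_rate = 5e4,
                           burst = list(freq_hz = 5e3, decay_s = 3e-4),
                           noise_floor_db = 20,
                           threshold_db = config$threshold_db, seed = seeds[4])
  det <- detect_hits(wav, threshold_db = config$threshold_db,
                     timing = config$timing)
  det <- assign_hits_to_quadrants(det, cycles)
  qcounts <- vapply(paste0("Q", 1:4),
                    function(q) sum(!is.na(det$quadrant) & det$quadrant == q),
                    numeric(1))
  audit <- list(simulated = nrow(truth_hits), detected = nrow(det),
                per_quadrant = qcounts,
                off_cycle = attr(det, "off_cycle"),
                conserved = sum(qcounts) + attr(det, "off_cycle") == nrow(det))

  ## 3. frozen PCA basis from synthetic developmental profiles: low-amplitude
  ##    (clinically-mild) and high-amplitude (clinically-severe) knees
  ndev <- config$n_developmental
  n_severe <- max(1, round(ndev * 3 / 8))
  dev_profiles <- lapply(seq_len(ndev), function(i) {
    severe <- i > ndev - n_severe
    amp <- config$params$amplitude
    amp$mean_excess_db <- if (severe) 3 * amp$mean_excess_db else amp$mean_excess_db
    h <- simulate_hit_stream(cycles, total_hits = if (severe) 250 else 80,
                             quadrant_proportions = config$params$quadrant_proportions,
                             amplitude = amp, threshold_db = config$threshold_db,
                             seed = seeds[5] + i)
    feature_profile(h, config$bins)
  })
  basis <- fit_pca_basis(dev_profiles, n_components = 3)
  eval_scores <- project_candidates(feature_profile(det, config$bins), basis)

  ## 4. reproducibility models
  rel1 <- fit_day_one_model(tab)
  rel2 <- fit_longitudinal_model(tab)

  ## 5. association model
  sel <- forward_select(tab, candidates = config$candidate_pool)
  assoc <- fit_final_model(tab, sel$selected)

  ## 6. quadrant summary across the cohort (per-set counts drawn from each
  ##    row's biomarker value under the configured quadrant proportions)
  set.seed(seeds[6])
  day1 <- tab[tab$day_index == 1 & tab$session == 1, ]
  qmat <- t(vapply(pmax(0, round(day1$biomarker_value)), function(n) {
    drop(rmultinom(1, n, config$params$quadrant_proportions))
  }, numeric(4)))
  qdf <- data.frame(q1 = qmat[, 1], q2 = qmat[, 2], q3 = qmat[, 3],
                    q4 = qmat[, 4], kl_grade = day1$kl_grade)
  qsummary <- quadrant_hit_distribution(qdf)

  ## 7. trial power from fitted components
  pw <- simulate_trial_power(trial_spec(
    n_per_group = 25, effect_fraction = config$power_effect,
    alpha = config$power_alpha,
    baseline_mean = unname(assoc$coefficients["intercept"]),
    sd_between_participant = assoc$sd_participant,
    sd_residual = assoc$sd_residual,
    n_replicates = config$power_replicates, seed = seeds[7]))

  bundle <- list(measurements = tab,
                 signals = list(trace = trace, cycles = cycles,
                                hits_truth = truth_hits, hits_detected = det),
                 detection_audit = audit,
                 pca = list(basis = basis, eval_scores = eval_scores),
                 reliability_day1 = rel1,
                 reliability_longitudinal = rel2,
                 association = list(selection = sel, fit = assoc),
                 quadrant_summary = qsummary,
                 power = pw,
                 provenance = list(seed = config$seed,
                                   config_hash = config$config_hash))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- sprintf("# seed %d config %s", config$seed, config$config_hash)
    wt <- function(df, name) {
      p <- file.path(config$out_dir, name)
      writeLines(prov, p)
      suppressWarnings(write.table(df, p, sep = ",", row.names = FALSE,
                                   append = TRUE, qmethod = "double"))
    }
    wt(tab, "measurements.csv")
    wt(profile_confidence_intervals(rel1, level = 0), "reliability_day1.csv")
    wt(profile_confidence_intervals(rel2, level = 0), "reliability_longitudinal.csv")
    wt(qsummary, "quadrant_summary.csv")
  }
  bundle
}
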
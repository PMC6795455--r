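## Parameter-recovery experiments. The clinical recordings behind the
## published variance-component and association estimates are not public, so
## the pipeline is validated by recovery: the generator is configured with
## the published point estimates as generating truths and the fitted models
## must give them back. These functions define those study conditions
## canonically so tests and scripts cannot drift apart.

#' Day-one variance-component recovery experiment
#'
#' Simulates the day-1 design (each participant measured in one session by
#' each of 3 practitioners, 2 sets per session) with the published unadjusted
#' day-one variance components as generating truths — patient 82.06,
#' session-in-patient 46.02, practitioner 6.05, residual 18.74 hits — with
#' machine offsets and covariate effects zeroed, then fits the day-one REML
#' model.
#'
#' @param n_patients simulated participants (default 500).
#' @param seed integer seed.
#' @param truth named numeric of generating SDs; override to run the same
#'   experiment under other conditions.
#' @return list: `truth`, `fit` (a `variance_components`), `estimates`
#'   (named vector aligned with `truth`).
#' @export
recover_day_one_components <- function(n_patients = 500, seed = 1L,
                                       truth = c(sd_patient = 82.06,
                                                 sd_session_in_patient = 46.02,
                                                 sd_rp = 6.05,
                                                 sd_residual = 18.74)) {
  design <- study_design(n_participants = n_patients, n_days = 1, n_weeks = 1)
  params <- generative_params(kl_contrasts = c(0, 0, 0), weight_coef = 0,
                              contralateral_pain_coef = 0,
                              sd_patient = truth[["sd_patient"]],
                              sd_session_in_patient = truth[["sd_session_in_patient"]],
                              sd_day_in_patient = 0,
                              sd_rp = truth[["sd_rp"]],
                              sd_residual = truth[["sd_residual"]],
                              machine_offsets = c(0, 0, 0))
  tab <- simulate_measurement_table(design, params, seed = seed)
  fit <- fit_day_one_model(tab)
  list(truth = truth, fit = fit, estimates = fit$estimates[names(truth)])
}

#' Longitudinal variance-component recovery experiment
#'
#' As [recover_day_one_components()], but over repeated measurement days
#' with the published longitudinal components as truths — day-in-patient
#' 55.75, patient 79.15, practitioner 47.22, residual 19.42 hits — and a
#' longitudinal REML fit.
#'
#' @param n_patients simulated participants (default 500).
#' @param n_days measurement days per participant (default 6).
#' @param seed integer seed.
#' @param truth named numeric of generating SDs.
#' @return list: `truth`, `fit`, `estimates`.
#' @export
recover_longitudinal_components <- function(n_patients = 500, n_days = 6,
                                            seed = 1L,
                                            truth = c(sd_day_in_patient = 55.75,
                                                      sd_patient = 79.15,
                                                      sd_rp = 47.22,
                                                      sd_residual = 19.42)) {
  design <- study_design(n_participants = n_patients, n_days = n_days,
                         n_weeks = 1)
  params <- generative_params(kl_contrasts = c(0, 0, 0), weight_coef = 0,
                              contralateral_pain_coef = 0,
                              sd_patient = truth[["sd_patient"]],
                              sd_session_in_patient = 0,
                              sd_day_in_patient = truth[["sd_day_in_patient"]],
                              sd_rp = truth[["sd_rp"]],
                              sd_residual = truth[["sd_residual"]],
                              machine_offsets = c(0, 0, 0))
  tab <- simulate_measurement_table(design, params, seed = seed)
  fit <- fit_longitudinal_model(tab)
  list(truth = truth, fit = fit, estimates = fit$estimates[names(truth)])
}

#' Association-model recovery experiment
#'
#' Replicated recovery of the published association-model parameters:
#' intercept 160.13 hits, KL successive-difference contrasts, weight 2.06
#' hits/kg, contralateral pain 57.05 hits, participant SD 93.17, residual SD
#' 22.51. Each replicate simulates participants with 2 measurements each
#' from this model, refits by REML with the same contrast coding, and the
#' estimates are averaged over replicates.
#'
#' @param n_participants per replicate (default 1000).
#' @param n_replicates number of seeded replicates (default 50).
#' @param seed integer master seed; replicate seeds are derived from it.
#' @return list: `truth` (named vector), `mean_estimates`, `replicates`
#'   (replicate x parameter matrix), `se_truth` (empirical SD of each
#'   estimator across replicates).
#' @export
recover_association_model <- function(n_participants = 1000,
                                      n_replicates = 50, seed = 1L) {
  truth <- c(intercept = 160.13, kl_1_vs_2 = -81.77, kl_2_vs_3 = 22.54,
             kl_3_vs_4 = 38.39, weight = 2.06, contralateral_pain = 57.05,
             sd_participant = 93.17, sd_residual = 22.51)
  design <- study_design(n_participants = n_participants, n_days = 1,
                         n_weeks = 1, n_practitioners_day1 = 1)
  params <- generative_params(sd_patient = 93.17, sd_session_in_patient = 0,
                              sd_day_in_patient = 0, sd_rp = 0,
                              sd_residual = 22.51, machine_offsets = c(0, 0, 0))
  seeds <- derive_seeds(seed, n_replicates)
  reps <- t(vapply(seq_len(n_replicates), function(r) {
    tab <- simulate_measurement_table(design, params, seed = seeds[r])
    fit <- fit_final_model(tab, c("kl_grade", "weight", "contralateral_pain"))
    c(fit$coefficients[c("intercept", "kl_1_vs_2", "kl_2_vs_3", "kl_3_vs_4",
                         "weight", "contralateral_pain")],
      sd_participant = fit$sd_participant, sd_residual = fit$sd_residual)
  }, numeric(8)))
  colnames(reps) <- names(truth)
  list(truth = truth,
       mean_estimates = colMeans(reps),
       replicates = reps,
       se_truth = apply(reps, 2, sd))
}
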
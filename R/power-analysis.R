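## Simulation-based power and sample-size calculation for a notional two-arm
## trial whose outcome is a candidate biomarker (e.g. "number of hits"),
## parameterized by the variance components of the fitted mixed models. Each
## simulated participant contributes the mean of their repeated measurements;
## the pre-declared analysis is a two-sided two-sample comparison of those
## participant means.

#' Specification of a notional two-arm trial
#'
#' @param n_per_group participants per arm.
#' @param effect_fraction fractional reduction in the treated-arm mean
#'   (e.g. 0.5 for a 50% reduction); 0 gives a null trial for type-I
#'   calibration.
#' @param alpha two-sided significance level.
#' @param baseline_mean control-arm mean outcome.
#' @param sd_between_participant,sd_residual variance components (SD scale)
#'   of the outcome's mixed model.
#' @param measurements_per_participant repeated measurements averaged per
#'   participant.
#' @param n_replicates simulation replicates (>= 100 for reporting).
#' @param seed integer seed.
#' @return an object of class `trial_spec`.
#' @export
trial_spec <- function(n_per_group, effect_fraction = 0.5, alpha = 0.05,
                       baseline_mean = 160.13,
                       sd_between_participant = 93.17, sd_residual = 22.51,
                       measurements_per_participant = 1,
                       n_replicates = 1000, seed = 1L) {
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("effect_fraction must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_per_group < 2) stop("need at least 2 participants per group")
  if (n_replicates < 100) stop("use >= 100 replicates for a reportable power estimate")
  structure(list(n_per_group = as.integer(n_per_group),
                 effect_fraction = effect_fraction, alpha = alpha,
                 baseline_mean = baseline_mean,
                 sd_between_participant = sd_between_participant,
                 sd_residual = sd_residual,
                 measurements_per_participant = as.integer(measurements_per_participant),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Simulate the power of a two-arm trial
#'
#' For each replicate, draws participant-level outcome means in both arms
#' from the Gaussian mixed model (between-participant effect plus the mean of
#' `measurements_per_participant` residuals), reduces the treated-arm mean by
#' `effect_fraction`, and applies a two-sided Welch t test at level `alpha`.
#' Power is the rejection fraction, with an exact binomial confidence
#' interval.
#'
#' @param spec a [trial_spec()].
#' @return an object of class `power_estimate`: `power`, `ci` (95% binomial),
#'   `n_rejections`, `n_replicates`, `spec`.
#' @export
simulate_trial_power <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  sd_mean <- sqrt(spec$sd_between_participant^2 +
                    spec$sd_residual^2 / spec$measurements_per_participant)
  mu_c <- spec$baseline_mean
  mu_t <- spec$baseline_mean * (1 - spec$effect_fraction)
  rej <- logical(spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    ctrl <- rnorm(n, mu_c, sd_mean)
    trt <- rnorm(n, mu_t, sd_mean)
    rej[r] <- t.test(ctrl, trt)$p.value < spec$alpha
  }
  k <- sum(rej)
  ci <- stats::binom.test(k, spec$n_replicates)$conf.int
  structure(list(power = k / spec$n_replicates, ci = as.numeric(ci),
                 n_rejections = k, n_replicates = spec$n_replicates,
                 spec = spec),
            class = "power_estimate")
}

#' Smallest per-group sample size reaching a target power
#'
#' Bisection over `n_per_group`, evaluating [simulate_trial_power()] with a
#' fixed seed at every candidate n (common random-number stream, so the
#' estimated power curve is monotone up to Monte-Carlo noise). The upper
#' bracket is grown geometrically from an analytic two-sample normal
#' starting point.
#'
#' @param target_power desired power, in `(alpha, 1)`.
#' @param spec a [trial_spec()]; its `n_per_group` is ignored.
#' @param n_max largest n considered before declaring the target unreachable.
#' @return list with `n_per_group` and `achieved_power` (the simulated power
#'   at the returned n).
#' @export
required_n <- function(target_power, spec, n_max = 5000) {
  stopifnot(inherits(spec, "trial_spec"))
  if (target_power <= spec$alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)")
  power_at <- function(n) {
    s <- spec
    s$n_per_group <- as.integer(n)
    simulate_trial_power(s)$power
  }
  delta <- spec$baseline_mean * spec$effect_fraction
  sd_mean <- sqrt(spec$sd_between_participant^2 +
                    spec$sd_residual^2 / spec$measurements_per_participant)
  guess <- if (delta > 0) {
    tryCatch(ceiling(power.t.test(delta = delta, sd = sd_mean,
                                  sig.level = spec$alpha,
                                  power = target_power)$n),
             error = function(e) 8)
  } else n_max
  lo <- 2L
  hi <- as.integer(min(n_max, max(4, guess)))
  while (power_at(hi) < target_power) {
    lo <- hi
    hi <- as.integer(min(n_max, hi * 2))
    if (hi >= n_max && power_at(n_max) < target_power)
      stop("target power unreachable with n_per_group <= ", n_max)
    if (hi == lo) break
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  list(n_per_group = hi, achieved_power = power_at(hi))
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Simulated power: %.3f (95%% CI %.3f-%.3f) over %d replicates\n",
              x$power, x$ci[1], x$ci[2], x$n_replicates))
  cat(sprintf("  n/group %d, %.0f%% reduction from %.1f, alpha %.3f\n",
              x$spec$n_per_group, 100 * x$spec$effect_fraction,
              x$spec$baseline_mean, x$spec$alpha))
  invisible(x)
}
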
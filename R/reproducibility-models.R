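## Variance-component reproducibility models for a candidate biomarker,
## fitted by REML. Two models: a 'day one' model with a session-within-
## participant random effect (sensor re-application by a different
## practitioner each session) and a longitudinal model with a day-within-
## participant random effect. Both include machine fixed effects and crossed
## participant and practitioner random effects.

## Internal: prepare the model frame shared by both reproducibility models.
vc_model_frame <- function(table, adjust_covariates) {
  need <- c("participant", "day_index", "session", "set", "practitioner",
            "machine", "biomarker_value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  d <- data.frame(
    value = table$biomarker_value,
    patient = factor(table$participant),
    rp = factor(table$practitioner),
    machine = factor(paste("JAAS", table$machine)),
    session_id = factor(paste(table$participant, table$day_index, table$session)),
    day_id = factor(paste(table$participant, table$day_index)))
  if (adjust_covariates) {
    for (v in c("kl_grade", "weight", "contralateral_pain")) {
      if (!v %in% names(table)) stop("covariate adjustment needs column ", v)
    }
    d$kl <- factor(table$kl_grade, levels = sort(unique(table$kl_grade)))
    if (nlevels(d$kl) > 1)
      contrasts(d$kl) <- kl_contrast_matrix(nlevels(d$kl))
    d$weight_c <- table$weight - mean(table$weight)
    d$pain <- table$contralateral_pain
  }
  d
}

## Internal: model right-hand side; machine fixed effects and the
## practitioner random effect are only identifiable with > 1 level and are
## dropped (their SD reported as NA) on degenerate designs.
vc_rhs <- function(d, nested_term, adjust_covariates) {
  terms <- c(if (nlevels(d$machine) > 1) "machine",
             "(1 | patient)",
             if (nlevels(d$rp) > 1) "(1 | rp)",
             nested_term)
  if (adjust_covariates) terms <- c("kl", "weight_c", "pain", terms)
  paste(terms, collapse = " + ")
}

## Internal: pull SDs, machine contrasts and flags out of a fitted merMod.
vc_extract <- function(fit, model_tag, adjusted) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i) == 0) NA_real_ else vc$sdcor[i]
  }
  est <- c(sd_patient = sd_of("patient"),
           sd_rp = sd_of("rp"),
           sd_residual = sd_of("Residual"))
  est <- if (model_tag == "day_one")
    c(est, sd_session_in_patient = sd_of("session_id"))
  else
    c(est, sd_day_in_patient = sd_of("day_id"))
  fe <- lme4::fixef(fit)
  mc <- fe[grepl("^machine", names(fe))]
  names(mc) <- sub("^machine", "", names(mc))
  structure(list(model_tag = model_tag, covariate_adjusted = adjusted,
                 estimates = est, machine_contrasts = mc,
                 singular = lme4::isSingular(fit, tol = 1e-5),
                 reml_loglik = as.numeric(logLik(fit)),
                 fit = fit),
            class = "variance_components")
}

#' Fit the day-one reproducibility model
#'
#' Gaussian linear mixed model for day-1 measurements, estimated by REML:
#' machine fixed effects (reference machine JAAS 1), crossed random
#' intercepts for participant and practitioner, a session-within-participant
#' random intercept capturing sensor re-application, and a residual
#' (between-set, within-session) error. Variance estimates may legitimately
#' land on the zero boundary; singular fits are reported through the
#' `singular` flag, not as errors.
#'
#' @param table a measurement table (see [simulate_measurement_table()]); only
#'   rows with `day_index == 1` are used.
#' @param adjust_covariates also include KL grade (successive-difference
#'   coding), centered weight and contralateral pain as fixed effects.
#' @return an object of class `variance_components` with `estimates`
#'   (`sd_patient`, `sd_rp`, `sd_residual`, `sd_session_in_patient`),
#'   `machine_contrasts`, the REML log-likelihood and the underlying fit.
#' @export
fit_day_one_model <- function(table, adjust_covariates = FALSE) {
  table <- table[table$day_index == 1, , drop = FALSE]
  if (nrow(table) == 0) stop("no day-1 rows in the table")
  sess_per_patient <- tapply(table$session, table$participant,
                             function(s) length(unique(s)))
  sets_per_session <- tapply(table$set, paste(table$participant, table$session),
                             function(s) length(unique(s)))
  if (max(sess_per_patient) < 2 || max(sets_per_session) < 2)
    stop("day-one model needs >= 2 sessions per participant and >= 2 sets per session")
  d <- vc_model_frame(table, adjust_covariates)
  rhs <- vc_rhs(d, "(1 | session_id)", adjust_covariates)
  fit <- lme4::lmer(as.formula(paste("value ~", rhs)), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc_extract(fit, "day_one", adjust_covariates)
}

#' Fit the longitudinal reproducibility model
#'
#' As [fit_day_one_model()], but across all measurement days, with a
#' day-within-participant random intercept in place of the session effect.
#'
#' @inheritParams fit_day_one_model
#' @return an object of class `variance_components` with
#'   `sd_day_in_patient` instead of the session component.
#' @export
fit_longitudinal_model <- function(table, adjust_covariates = FALSE) {
  days_per_patient <- tapply(table$day_index, table$participant,
                             function(s) length(unique(s)))
  if (max(days_per_patient) < 2)
    stop("longitudinal model needs >= 2 days per participant")
  d <- vc_model_frame(table, adjust_covariates)
  rhs <- vc_rhs(d, "(1 | day_id)", adjust_covariates)
  fit <- lme4::lmer(as.formula(paste("value ~", rhs)), data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc_extract(fit, "longitudinal", adjust_covariates)
}

#' Profile-likelihood confidence intervals for a fitted model
#'
#' Intervals based on the profiled (restricted) likelihood, the same method
#' used for all intervals reported by the pipeline. Standard-deviation
#' intervals are truncated at 0; a component estimated at the boundary can
#' therefore report a lower limit of exactly 0. If profiling fails for a
#' parameter (which can happen for near-singular variance components), a
#' widest-bracket fallback `[0, Inf)` for SDs or a Wald interval for fixed
#' effects is substituted and flagged in the `method` column.
#'
#' @param object a `variance_components` or `association_fit` object (or any
#'   list carrying a merMod in `$fit`).
#' @param level confidence level; `level = 0` returns degenerate intervals at
#'   the point estimates.
#' @return data.frame with columns `parameter`, `estimate`, `lcl`, `ucl`,
#'   `method`.
#' @export
profile_confidence_intervals <- function(object, level = 0.95) {
  fit <- object$fit
  stopifnot(inherits(fit, "merMod"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_names <- ifelse(vc$grp == "Residual", "sigma",
                     paste0("sd_(Intercept)|", vc$grp))
  est <- c(setNames(vc$sdcor, sd_names), lme4::fixef(fit))
  if (level == 0)
    return(data.frame(parameter = names(est), estimate = unname(est),
                      lcl = unname(est), ucl = unname(est),
                      method = "degenerate", stringsAsFactors = FALSE))
  ci <- tryCatch(
    suppressWarnings(stats::confint(fit, method = "profile", level = level,
                                    oldNames = FALSE, quiet = TRUE)),
    error = function(e) NULL)
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    lcl = NA_real_, ucl = NA_real_, method = "profile",
                    stringsAsFactors = FALSE)
  is_sd <- seq_along(est) <= length(sd_names)
  if (!is.null(ci)) {
    m <- match(out$parameter, rownames(ci))
    out$lcl <- ci[m, 1]
    out$ucl <- ci[m, 2]
  }
  bad <- is.na(out$lcl) | is.na(out$ucl)
  if (any(bad & is_sd)) { # widest-bracket fallback for unprofilable SDs
    out$lcl[bad & is_sd] <- 0
    out$ucl[bad & is_sd] <- Inf
    out$method[bad & is_sd] <- "fallback_bracket"
  }
  if (any(bad & !is_sd)) {
    wald <- suppressWarnings(stats::confint(fit, method = "Wald", level = level))
    m <- match(out$parameter[bad & !is_sd], rownames(wald))
    out$lcl[bad & !is_sd] <- wald[m, 1]
    out$ucl[bad & !is_sd] <- wald[m, 2]
    out$method[bad & !is_sd] <- "wald_fallback"
  }
  out$lcl[is_sd] <- pmax(0, out$lcl[is_sd])
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$model_tag,
      if (x$covariate_adjusted) ", covariate-adjusted" else "", ")\n", sep = "")
  print(round(x$estimates, 2))
  if (length(x$machine_contrasts)) {
    cat("Machine contrasts (vs JAAS 1):\n")
    print(round(x$machine_contrasts, 2))
  }
  if (x$singular) cat("note: fit is singular (a variance component is at the boundary)\n")
  invisible(x)
}
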
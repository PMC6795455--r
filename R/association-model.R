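## Association model for a candidate biomarker: a Gaussian linear mixed model
## with a participant random intercept, built by forward selection over a
## candidate covariate pool using likelihood-ratio tests (ML fits, p < 0.1 to
## enter) and refitted by REML. KL grade uses successive-difference contrasts
## so the intercept reads as the average response across KL levels at mean
## weight and no contralateral pain.

#' Default candidate covariate pool for forward selection
#' @export
default_candidate_pool <- function() {
  c("kl_grade", "weight", "contralateral_pain", "age", "sex", "bmi",
    "womac_pain", "womac_stiffness", "womac_function", "vas_pain_worst_knee")
}

## Internal: model frame for the association model. Weight is centered at the
## sample mean; KL is a factor under successive-difference contrasts.
assoc_model_frame <- function(table, covariates) {
  d <- data.frame(value = table$biomarker_value,
                  participant = factor(table$participant))
  for (v in covariates) {
    if (!v %in% names(table)) stop("table lacks candidate covariate ", v)
    col <- table[[v]]
    if (v == "kl_grade") {
      col <- factor(col, levels = sort(unique(col)))
      if (nlevels(col) > 1) contrasts(col) <- kl_contrast_matrix(nlevels(col))
    } else if (v == "weight") {
      col <- col - mean(col, na.rm = TRUE)
    } else if (is.character(col)) {
      col <- factor(col)
    }
    d[[v]] <- col
  }
  d
}

#' Likelihood-ratio test p-value for nested model fits
#'
#' Twice the log-likelihood difference referred to a chi-square distribution
#' with degrees of freedom equal to the parameter-count difference. Both
#' fits must be maximum-likelihood (not REML) fits of the same response;
#' identical fits give p = 1 by convention.
#'
#' @param null_fit,alt_fit nested model fits with `logLik` methods; `alt_fit`
#'   must have at least as many parameters.
#' @return p-value in `[0, 1]`.
#' @export
lrt_pvalue <- function(null_fit, alt_fit) {
  for (f in list(null_fit, alt_fit))
    if (inherits(f, "merMod") && lme4::isREML(f))
      warning("LRT comparison expects ML (not REML) fits")
  ll0 <- logLik(null_fit)
  ll1 <- logLik(alt_fit)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("models are not nested: the alternative has fewer parameters")
  stat <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  if (df == 0) {
    if (stat < 1e-6) return(1)
    stop("models have equal parameter counts but different likelihoods; not nested")
  }
  pchisq(stat, df, lower.tail = FALSE)
}

#' Forward selection of covariates by likelihood-ratio test
#'
#' Starting from the random-intercept-only model, repeatedly fits (by maximum
#' likelihood) one-term extensions, adds the candidate with the smallest LRT
#' p-value while that p-value is below the cutoff, and stops otherwise.
#' Candidates whose addition does not increase the fixed-effect count (rank
#' deficiency / collinearity) or whose fit fails are skipped and recorded in
#' the trace. Deterministic given the data.
#'
#' @param table measurement table with `biomarker_value`, `participant` and
#'   the candidate columns.
#' @param candidates character vector of candidate covariate names (default
#'   [default_candidate_pool()], intersected with available columns).
#' @param cutoff significance cutoff to enter (default 0.1).
#' @return list with `selected` (ordered character vector) and `trace`
#'   (data.frame: step, candidate, p_value, entered, note).
#' @export
forward_select <- function(table, candidates = default_candidate_pool(),
                           cutoff = 0.1) {
  candidates <- intersect(candidates, names(table))
  d <- assoc_model_frame(table, candidates)
  d <- d[complete.cases(d), , drop = FALSE]
  fml <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    as.formula(paste("value ~", rhs, "+ (1 | participant)"))
  }
  ml_fit <- function(terms) {
    lme4::lmer(fml(terms), data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  selected <- character(0)
  remaining <- candidates
  base <- ml_fit(selected)
  trace <- data.frame(step = integer(0), candidate = character(0),
                      p_value = numeric(0), entered = logical(0),
                      note = character(0), stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    pvals <- rep(NA_real_, length(remaining))
    notes <- rep("", length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      alt <- tryCatch(ml_fit(c(selected, remaining[i])), error = function(e) NULL)
      if (is.null(alt)) { notes[i] <- "fit failed"; next }
      extra_df <- attr(logLik(alt), "df") - attr(logLik(base), "df")
      if (extra_df <= 0) { notes[i] <- "collinear; skipped"; next }
      pvals[i] <- lrt_pvalue(base, alt)
      fits[[i]] <- alt
    }
    if (all(is.na(pvals))) {
      trace <- rbind(trace, data.frame(step = step, candidate = remaining,
                                       p_value = NA_real_, entered = FALSE,
                                       note = notes, stringsAsFactors = FALSE))
      break
    }
    best <- which.min(pvals)
    enter <- pvals[best] < cutoff
    trace <- rbind(trace, data.frame(step = step, candidate = remaining[best],
                                     p_value = pvals[best], entered = enter,
                                     note = notes[best], stringsAsFactors = FALSE))
    dropped <- nzchar(notes) & is.na(pvals)
    if (any(dropped))
      trace <- rbind(trace, data.frame(step = step, candidate = remaining[dropped],
                                       p_value = NA_real_, entered = FALSE,
                                       note = notes[dropped], stringsAsFactors = FALSE))
    if (!enter) break
    selected <- c(selected, remaining[best])
    base <- fits[[best]]
    remaining <- setdiff(remaining, c(selected, remaining[dropped]))
  }
  list(selected = selected, trace = trace)
}

#' Fit the final association model by REML
#'
#' Gaussian linear mixed model for the biomarker with the selected fixed
#' effects and a participant random intercept, estimated by REML on complete
#' cases. KL grade enters under successive-difference contrasts (so the
#' intercept is the average over KL levels) and weight is centered at the
#' sample mean (so the intercept refers to an individual of mean weight).
#'
#' @param table measurement table.
#' @param selected character vector of covariates (e.g. the `selected`
#'   element of [forward_select()]).
#' @return an object of class `association_fit`: `coefficients` (named:
#'   `intercept`, `kl_1_vs_2`, ..., `weight`, `contralateral_pain`, ...),
#'   `sd_participant`, `sd_residual`, `n_rows_dropped` (incomplete cases),
#'   `selected`, and the underlying `fit`.
#' @export
fit_final_model <- function(table, selected) {
  d <- assoc_model_frame(table, selected)
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) == 0) stop("no complete cases for the selected covariates")
  rhs <- if (length(selected)) paste(selected, collapse = " + ") else "1"
  fit <- lme4::lmer(as.formula(paste("value ~", rhs, "+ (1 | participant)")),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  nm <- names(fe)
  nm[nm == "(Intercept)"] <- "intercept"
  nm <- sub("^kl_grade(\\d)vs(\\d)$", "kl_\\1_vs_\\2", nm)
  names(fe) <- nm
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = fe,
                 sd_participant = vc$sdcor[vc$grp == "participant"],
                 sd_residual = vc$sdcor[vc$grp == "Residual"],
                 n_rows_dropped = sum(!cc),
                 selected = selected,
                 fit = fit),
            class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat("Association model (REML), covariates:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)", "\n")
  print(round(x$coefficients, 2))
  cat("SD participant random effect:", round(x$sd_participant, 2),
      "  SD residual:", round(x$sd_residual, 2), "\n")
  if (x$n_rows_dropped > 0)
    cat("note:", x$n_rows_dropped, "incomplete rows dropped\n")
  invisible(x)
}
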
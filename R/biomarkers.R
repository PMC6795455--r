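## Candidate biomarkers per knee recording: "number of hits" above threshold,
## and the first three principal-component scores of quadrant-wise 2D
## histograms of (average signal level x peak amplitude) — the AE feature
## profile. The PCA basis is fitted once on a developmental subset and frozen;
## evaluation recordings are scored by projection only.

#' Bin grid for AE feature profiles
#'
#' @param asl_range dB range for average signal level bins.
#' @param amp_range dB range for peak amplitude bins; the lower edge should
#'   not sit below the detection threshold.
#' @param n_bins bins per axis (the profile is 4 quadrants x n_bins^2 cells).
#' @return an object of class `bin_config` with `asl_edges`, `amp_edges` and
#'   a `fingerprint` string used to prevent basis/profile grid mismatches.
#' @export
bin_config <- function(asl_range = c(30, 90), amp_range = c(36, 100), n_bins = 8) {
  if (n_bins < 1 || diff(asl_range) <= 0 || diff(amp_range) <= 0)
    stop("invalid bin configuration")
  asl_edges <- seq(asl_range[1], asl_range[2], length.out = n_bins + 1)
  amp_edges <- seq(amp_range[1], amp_range[2], length.out = n_bins + 1)
  structure(list(asl_edges = asl_edges, amp_edges = amp_edges, n_bins = n_bins,
                 fingerprint = paste(format(c(asl_edges, amp_edges), digits = 10),
                                     collapse = ",")),
            class = "bin_config")
}

#' Number of AE hits in a recording scope
#'
#' The primary candidate biomarker: the count of hits above the acquisition
#' threshold whose onset falls inside the scope window (one recorded set of 5
#' movements, by default the whole table).
#'
#' @param hits a hit table with `onset_time`.
#' @param window optional `c(t0, t1)` half-open window in seconds.
#' @return integer count.
#' @export
number_of_hits <- function(hits, window = NULL) {
  if (is.null(window)) return(nrow(hits))
  sum(hits$onset_time >= window[1] & hits$onset_time < window[2])
}

#' AE feature profile of a recording
#'
#' Per movement quadrant, a 2D histogram of (average signal level, peak
#' amplitude) over the configured bin grid. Only quadrant-labelled (on-cycle)
#' hits are counted, so the histogram total equals the on-cycle hit count.
#' Hits outside the bin ranges are clamped into the edge bins; the number
#' clamped is reported via the `clamped` attribute.
#'
#' @param hits a quadrant-labelled hit table (see
#'   [assign_hits_to_quadrants()]) with `asl_db` and `peak_db`.
#' @param bins a [bin_config()].
#' @param normalize divide counts by their total (default `FALSE`, so PC
#'   candidates carry intensity as well as shape information).
#' @return a 3D array of class `feature_profile`, dim (4, n_bins, n_bins)
#'   indexed (quadrant, asl bin, amplitude bin), with `bin_config`,
#'   `fingerprint`, `normalized` and `clamped` attributes.
#' @export
feature_profile <- function(hits, bins = bin_config(), normalize = FALSE) {
  stopifnot(inherits(bins, "bin_config"))
  nb <- bins$n_bins
  prof <- array(0, dim = c(4, nb, nb),
                dimnames = list(paste0("Q", 1:4), NULL, NULL))
  on_cycle <- hits[!is.na(hits$quadrant), , drop = FALSE]
  clamped <- 0L
  if (nrow(on_cycle) > 0) {
    clamp_bin <- function(x, edges) {
      i <- findInterval(x, edges, rightmost.closed = TRUE)
      pmin(pmax(i, 1L), length(edges) - 1L)
    }
    ia <- clamp_bin(on_cycle$asl_db, bins$asl_edges)
    ip <- clamp_bin(on_cycle$peak_db, bins$amp_edges)
    clamped <- sum(on_cycle$asl_db < bins$asl_edges[1] |
                     on_cycle$asl_db > bins$asl_edges[nb + 1] |
                     on_cycle$peak_db < bins$amp_edges[1] |
                     on_cycle$peak_db > bins$amp_edges[nb + 1])
    iq <- match(on_cycle$quadrant, paste0("Q", 1:4))
    for (k in seq_len(nrow(on_cycle)))
      prof[iq[k], ia[k], ip[k]] <- prof[iq[k], ia[k], ip[k]] + 1
  }
  if (normalize && sum(prof) > 0) prof <- prof / sum(prof)
  structure(prof, bin_config = bins, fingerprint = bins$fingerprint,
            normalized = normalize, clamped = clamped,
            class = "feature_profile")
}

## Internal: flatten a profile to the vector the PCA operates on.
flatten_profile <- function(profile) as.numeric(profile)

#' Fit the principal-component basis on developmental profiles
#'
#' Flattens each feature profile to a vector, column-mean-centers the stack
#' and extracts the leading right singular vectors. The first three component
#' scores are the PCA-based candidate biomarkers. The basis is meant to be
#' fitted once, on the developmental subset only, then frozen; evaluation
#' recordings are scored with [project_candidates()].
#'
#' @param profiles list of `feature_profile`s on identical bin grids.
#' @param n_components number of components to retain (default 3).
#' @return an object of class `pca_basis`: `center` (bin-wise mean),
#'   `loadings` (bins x components, orthonormal), `explained_var`
#'   (fractions, non-increasing), `fingerprint`, `scores` (fit-time scores of
#'   the developmental profiles).
#' @export
fit_pca_basis <- function(profiles, n_components = 3) {
  if (length(profiles) < n_components + 1)
    stop("need at least n_components + 1 profiles to fit the basis")
  fps <- vapply(profiles, function(p) attr(p, "fingerprint"), character(1))
  if (length(unique(fps)) != 1)
    stop("profiles were built on different bin grids; refuse to mix them")
  X <- do.call(rbind, lapply(profiles, flatten_profile))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_var = ev[seq_len(k)],
                 fingerprint = fps[1],
                 scores = pc$x[, seq_len(k), drop = FALSE]),
            class = "pca_basis")
}

#' Project a feature profile onto a frozen PCA basis
#'
#' @param profile a `feature_profile` on the basis's bin grid.
#' @param basis a `pca_basis` from [fit_pca_basis()].
#' @return named numeric vector of component scores (pc1, pc2, ...).
#' @export
project_candidates <- function(profile, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  if (!identical(attr(profile, "fingerprint"), basis$fingerprint))
    stop("profile bin grid does not match the PCA basis fingerprint")
  s <- drop((flatten_profile(profile) - basis$center) %*% basis$loadings)
  names(s) <- paste0("pc", seq_along(s))
  s
}

#' Full biomarker set for one recording
#'
#' Convenience wrapper: number of hits, per-quadrant counts and (optionally)
#' the three PC scores for one set of movements.
#'
#' @param hits quadrant-labelled hit table for the recording.
#' @param basis optional frozen `pca_basis`; if supplied, PC scores are
#'   computed on the basis's bin grid.
#' @param bins bin grid used when `basis` is `NULL`.
#' @return one-row data.frame: `n_hits`, `q1`..`q4`, `off_cycle`, and
#'   `pc1`..`pc3` when a basis is given.
#' @export
biomarker_set <- function(hits, basis = NULL, bins = bin_config()) {
  qc <- vapply(paste0("Q", 1:4),
               function(q) sum(!is.na(hits$quadrant) & hits$quadrant == q),
               numeric(1))
  out <- data.frame(n_hits = nrow(hits), q1 = qc[1], q2 = qc[2],
                    q3 = qc[3], q4 = qc[4],
                    off_cycle = sum(is.na(hits$quadrant)))
  if (!is.null(basis)) {
    bc <- attr_bin_config(basis, bins)
    s <- project_candidates(feature_profile(hits, bc), basis)
    out$pc1 <- s[1]; out$pc2 <- s[2]; out$pc3 <- s[3]
  }
  rownames(out) <- NULL
  out
}

## Internal: recover a bin_config matching a basis fingerprint.
attr_bin_config <- function(basis, bins) {
  if (identical(bins$fingerprint, basis$fingerprint)) return(bins)
  stop("supply the bin_config the basis was fitted with")
}

#' Per-quadrant hit-count distributions by OA severity group
#'
#' Summarizes per-set quadrant counts for participants with KL grade 1
#' against those with KL 2 or higher — the grouping under which hit counts
#' are consistently highest in quadrants Q1 and Q4.
#'
#' @param quadrant_counts data.frame with one row per recording set: columns
#'   `q1`..`q4` and `kl_grade`.
#' @return data.frame with one row per group x quadrant: `group`, `quadrant`,
#'   `median`, `iqr_lo`, `iqr_hi`, `n_sets`.
#' @export
quadrant_hit_distribution <- function(quadrant_counts) {
  need <- c("q1", "q2", "q3", "q4", "kl_grade")
  if (!all(need %in% names(quadrant_counts)))
    stop("quadrant_counts must have columns ", paste(need, collapse = ", "))
  group <- ifelse(quadrant_counts$kl_grade <= 1, "KL1", "KL2+")
  out <- expand.grid(group = c("KL1", "KL2+"), quadrant = paste0("Q", 1:4),
                     stringsAsFactors = FALSE)
  stats_for <- function(g, q) {
    x <- quadrant_counts[group == g, tolower(q)]
    if (length(x) == 0) x <- 0
    c(median(x), quantile(x, 0.25), quantile(x, 0.75), sum(group == g))
  }
  m <- t(mapply(stats_for, out$group, out$quadrant))
  out$median <- m[, 1]; out$iqr_lo <- m[, 2]; out$iqr_hi <- m[, 3]
  out$n_sets <- m[, 4]
  out[order(out$group, out$quadrant), ]
}
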
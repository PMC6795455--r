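## Threshold-crossing AE hit detection, reproducing the event-based recording
## mode of the acquisition hardware: a hit opens when the rectified signal
## reaches the dB threshold and closes once it has stayed below threshold for
## the hit-definition time; a lockout period follows closure.

#' Convert microvolts to decibels re 1 microvolt
#'
#' The acquisition threshold (36 dB by default throughout the package) is
#' expressed on this scale: `20 * log10(v / 1uV)`.
#'
#' @param v voltage in microvolts, strictly positive.
#' @return amplitude in dB re 1 microvolt.
#' @export
volts_to_db <- function(v) {
  if (any(v <= 0)) stop("voltage must be strictly positive to convert to dB")
  20 * log10(v)
}

#' @rdname volts_to_db
#' @param db amplitude in dB re 1 microvolt.
#' @export
db_to_volts <- function(db) 10^(db / 20)

#' Hit-timing parameters for the detector
#'
#' Standard AE acquisition timing constants. The defaults are conventional
#' values for wide-band AE acquisition; all are configurable.
#'
#' @param peak_definition_time s; retained as acquisition metadata (the peak
#'   is taken over the whole hit window here).
#' @param hit_definition_time s of continuous sub-threshold signal that
#'   closes an open hit; must be positive.
#' @param hit_lockout_time s after closure during which no new hit may open.
#' @return an object of class `hit_timing`.
#' @export
hit_timing <- function(peak_definition_time = 200e-6,
                       hit_definition_time = 800e-6,
                       hit_lockout_time = 1000e-6) {
  if (hit_definition_time <= 0) stop("hit_definition_time must be positive")
  if (peak_definition_time < 0 || hit_lockout_time < 0)
    stop("timing parameters must be non-negative")
  structure(list(peak_definition_time = peak_definition_time,
                 hit_definition_time = hit_definition_time,
                 hit_lockout_time = hit_lockout_time),
            class = "hit_timing")
}

#' Detect AE hits in a waveform
#'
#' Sample-wise threshold crossing on the rectified signal: a hit opens at the
#' first sample whose rectified amplitude (in dB re 1 microvolt) reaches
#' `threshold_db`, and closes when the signal stays below threshold for
#' `hit_definition_time`. Sub-threshold gaps shorter than that stay inside
#' the hit. After closure no new hit opens for `hit_lockout_time`; crossings
#' during lockout are discarded. Per hit, the peak amplitude is the maximum
#' rectified sample over the hit window (first to last above-threshold
#' sample) and the average signal level (ASL) is the dB value of the mean
#' rectified voltage over that window, so ASL never exceeds the peak.
#'
#' @param w a `waveform` (see [simulate_waveform()]).
#' @param threshold_db detection threshold, dB re 1 microvolt (default 36,
#'   the acquisition setting used throughout).
#' @param timing a [hit_timing()].
#' @return a data.frame of hits ordered by onset: `onset_time`, `peak_db`,
#'   `asl_db`, `duration`, `channel`.
#' @export
detect_hits <- function(w, threshold_db = 36, timing = hit_timing()) {
  stopifnot(inherits(w, "waveform"))
  empty <- data.frame(onset_time = numeric(0), peak_db = numeric(0),
                      asl_db = numeric(0), duration = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE)
  x <- abs(w$samples)
  if (length(x) == 0) return(empty)
  if (!all(is.finite(x))) stop("waveform contains non-finite samples")
  fs <- w$sampling_rate
  thr <- db_to_volts(threshold_db)
  ## robust noise-floor estimate (median-based, insensitive to bursts)
  floor_db <- volts_to_db(max(median(x) / 0.6745, .Machine$double.xmin))
  if (threshold_db <= floor_db)
    warning("threshold (", threshold_db, " dB) is at or below the noise floor (",
            round(floor_db, 1), " dB); detections will be noise-dominated")
  above <- x >= thr
  if (!any(above)) return(empty)

  ## maximal runs of above-threshold samples
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]

  ## merge runs whose separating gap is shorter than the hit-definition time
  gap_samples <- ceiling(timing$hit_definition_time * fs)
  hit_start <- run_start[1]
  hit_end <- run_end[1]
  windows <- list()
  for (i in seq_along(run_start)[-1]) {
    if (run_start[i] - hit_end - 1L < gap_samples) {
      hit_end <- run_end[i]
    } else {
      windows[[length(windows) + 1L]] <- c(hit_start, hit_end)
      hit_start <- run_start[i]
      hit_end <- run_end[i]
    }
  }
  windows[[length(windows) + 1L]] <- c(hit_start, hit_end)

  ## lockout: a hit closes hit_definition_time after its last above-threshold
  ## sample and no new hit opens for hit_lockout_time after closure; a window
  ## outlasting the lockout opens at its first above-threshold sample past
  ## it. All timing is discretized to samples (ceiling) to keep boundaries
  ## exact.
  lock_samples <- ceiling(timing$hit_lockout_time * fs)
  keep <- list()
  allowed_idx <- 1L
  for (wnd in windows) {
    cand <- wnd[1]:wnd[2]
    cand <- cand[above[cand] & cand >= allowed_idx]
    if (length(cand) == 0) next
    keep[[length(keep) + 1L]] <- c(cand[1], wnd[2])
    allowed_idx <- wnd[2] + gap_samples + lock_samples
  }
  if (length(keep) == 0) return(empty)

  res <- do.call(rbind, lapply(keep, function(wnd) {
    seg <- x[wnd[1]:wnd[2]]
    data.frame(onset_time = w$start_time + (wnd[1] - 1) / fs,
               peak_db = volts_to_db(max(seg)),
               asl_db = volts_to_db(mean(seg)),
               duration = (wnd[2] - wnd[1]) / fs,
               channel = w$channel, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
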
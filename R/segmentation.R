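## Movement segmentation: from a goniometer angle trace, detect sit-stand-sit
## cycles and divide each into the four kinematic quadrants used to localize
## AE activity (Q1 ascending-acceleration, Q2 ascending-deceleration,
## Q3 descending-acceleration, Q4 descending-deceleration). "Ascending" means
## standing up, i.e. decreasing knee flexion.

#' Smooth an angle trace and compute derivatives
#'
#' Zero-phase low-pass filtering (2nd-order Butterworth applied forwards and
#' backwards) of the knee angle, followed by central-difference angular
#' velocity and acceleration. The default 2 Hz cutoff is far above the
#' sit-stand-sit cadence but suppresses goniometer noise.
#'
#' @param trace an `angle_trace` (data.frame with `time`, `angle` and a
#'   `sampling_rate` attribute).
#' @param cutoff_hz low-pass cutoff; must be below the Nyquist frequency.
#' @return a data.frame of class `kinematic_trace` with `time`, `angle`
#'   (smoothed), `velocity` (deg/s) and `acceleration` (deg/s^2); carries the
#'   `sampling_rate` attribute.
#' @export
smooth_and_differentiate <- function(trace, cutoff_hz = 2) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(trace$time))
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist frequency")
  if (!all(is.finite(trace$angle))) stop("angle trace contains non-finite values")
  if (any(diff(trace$time) <= 0)) stop("time must be strictly increasing")
  n <- nrow(trace)
  if (n < 24) stop("trace too short for zero-phase filtering")
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  ## odd-reflection padding keeps the filter's zero-state transient out of
  ## the trace (filtfilt alone would bend both ends toward zero)
  np <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  y <- trace$angle - trace$angle[1] # zero baseline kills the step transient
  padded <- c(2 * y[1] - y[(np + 1):2], y, 2 * y[n] - y[(n - 1):(n - np)])
  sm <- signal::filtfilt(bf, padded)[(np + 1):(np + n)] + trace$angle[1]
  dt <- 1 / fs
  cdiff <- function(y) {
    d <- numeric(length(y))
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
    d[1] <- (y[2] - y[1]) / dt
    d[n] <- (y[n] - y[n - 1]) / dt
    d
  }
  vel <- cdiff(sm)
  acc <- cdiff(vel)
  structure(data.frame(time = trace$time, angle = sm,
                       velocity = vel, acceleration = acc),
            sampling_rate = fs,
            class = c("kinematic_trace", "data.frame"))
}

#' Detect sit-stand-sit cycles in a kinematic trace
#'
#' A cycle is seeded by a downward crossing of the 50%-of-range angle level
#' (leaving the seated position) paired with the next upward crossing (the
#' return), then extended outwards to the adjacent local angle maxima (the
#' seated rests). The stand time is the angle minimum between the crossings.
#' A downward crossing with no return (the participant never sits back down)
#' is counted as an incomplete segment, reported via the `incomplete`
#' attribute, not as a cycle.
#'
#' @param kin a `kinematic_trace` from [smooth_and_differentiate()].
#' @param seated_angle,standing_angle nominal flexion angles, degrees;
#'   seated must exceed standing. Only their midpoint enters the rule, so
#'   segmentation is invariant to adding a constant to both.
#' @return a data.frame of class `movement_cycles`: `cycle_index`, `start`,
#'   `stand`, `end` (s); attribute `incomplete` counts half-movements.
#' @export
detect_cycles <- function(kin, seated_angle = 90, standing_angle = 0) {
  stopifnot(inherits(kin, "kinematic_trace"))
  if (seated_angle <= standing_angle) stop("seated_angle must exceed standing_angle")
  a <- kin$angle
  n <- length(a)
  mid <- (seated_angle + standing_angle) / 2
  down <- which(a[-n] >= mid & a[-1] < mid)
  up <- which(a[-n] < mid & a[-1] >= mid)
  cyc <- data.frame(cycle_index = integer(0), start = numeric(0),
                    stand = numeric(0), end = numeric(0))
  incomplete <- 0L
  prev_end_idx <- 0L
  k <- 0L
  tol <- 1e-6 * (seated_angle - standing_angle) # treats seated plateaus as flat
  for (d in down) {
    u <- up[up > d]
    if (length(u) == 0) { incomplete <- incomplete + 1L; next }
    u <- u[1]
    ## extend outwards to the adjacent local angle maxima (seated rests):
    ## walk while the angle keeps strictly rising away from the movement
    i0 <- d
    while (i0 > prev_end_idx + 1L && a[i0 - 1L] > a[i0] + tol) i0 <- i0 - 1L
    i1 <- u + 1L
    while (i1 < n && a[i1 + 1L] > a[i1] + tol) i1 <- i1 + 1L
    si <- d + which.min(a[d:u]) - 1L
    k <- k + 1L
    cyc <- rbind(cyc, data.frame(cycle_index = k, start = kin$time[i0],
                                 stand = kin$time[si], end = kin$time[i1]))
    prev_end_idx <- i1
  }
  structure(cyc, incomplete = incomplete,
            class = c("movement_cycles", "data.frame"))
}

#' Split cycles into the four movement quadrants
#'
#' Within each cycle the ascent (start to stand) is split at the time of
#' maximum angular speed into Q1 (ascending-acceleration) and Q2
#' (ascending-deceleration); the descent (stand to end) is split at its own
#' speed maximum into Q3 and Q4. On a symmetric raised-cosine cycle of
#' duration T this yields boundaries at T/4 and 3T/4. Ties in the speed
#' maximum are broken to the earliest sample.
#'
#' @param kin the `kinematic_trace` the cycles were detected on.
#' @param cycles a `movement_cycles` data.frame from [detect_cycles()].
#' @return `cycles` with columns `q2_start` and `q4_start` added; the four
#'   half-open quadrant intervals are `[start, q2_start)`, `[q2_start,
#'   stand)`, `[stand, q4_start)`, `[q4_start, end)`.
#' @export
quadrant_boundaries <- function(kin, cycles) {
  stopifnot(inherits(kin, "kinematic_trace"))
  speed <- abs(kin$velocity)
  peak_in <- function(t0, t1) {
    idx <- which(kin$time >= t0 & kin$time < t1)
    if (length(idx) == 0) return((t0 + t1) / 2)
    kin$time[idx[which.max(speed[idx])]] # which.max takes the earliest tie
  }
  cycles$q2_start <- mapply(peak_in, cycles$start, cycles$stand)
  cycles$q4_start <- mapply(peak_in, cycles$stand, cycles$end)
  cycles
}

#' Quadrant time intervals of segmented cycles
#'
#' @param cycles a `movement_cycles` data.frame carrying `q2_start` and
#'   `q4_start` (see [quadrant_boundaries()]).
#' @return a data.frame with one row per cycle x quadrant: `cycle_index`,
#'   `quadrant` ("Q1".."Q4"), `t0`, `t1`. Intervals are half-open `[t0, t1)`.
#' @export
quadrant_intervals <- function(cycles) {
  if (nrow(cycles) == 0 || is.null(cycles$q2_start))
    return(data.frame(cycle_index = integer(0), quadrant = character(0),
                      t0 = numeric(0), t1 = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(cycles)), function(i) {
    b <- c(cycles$start[i], cycles$q2_start[i], cycles$stand[i],
           cycles$q4_start[i], cycles$end[i])
    data.frame(cycle_index = cycles$cycle_index[i],
               quadrant = paste0("Q", 1:4),
               t0 = b[1:4], t1 = b[2:5], stringsAsFactors = FALSE)
  }))
}

#' Label hits with their movement quadrant
#'
#' Each hit whose onset falls inside a half-open quadrant interval `[t0, t1)`
#' receives that quadrant and cycle label (a hit exactly on the Q1/Q2
#' boundary therefore belongs to Q2). Hits landing between cycles (seated
#' rests) are labelled off-cycle (`NA` quadrant) and excluded from quadrant
#' analyses; their count is reported via the `off_cycle` attribute.
#'
#' @param hits a hit table with an `onset_time` column.
#' @param cycles segmented cycles with quadrant boundaries.
#' @return `hits` with `quadrant` and `cycle_index` columns (re)filled;
#'   attribute `off_cycle` gives the number of unlabelled hits.
#' @export
assign_hits_to_quadrants <- function(hits, cycles) {
  iv <- quadrant_intervals(cycles)
  quadrant <- rep(NA_character_, nrow(hits))
  cycle_index <- rep(NA_integer_, nrow(hits))
  if (nrow(hits) > 0 && nrow(iv) > 0) {
    for (j in seq_len(nrow(iv))) {
      inside <- hits$onset_time >= iv$t0[j] & hits$onset_time < iv$t1[j]
      quadrant[inside] <- iv$quadrant[j]
      cycle_index[inside] <- iv$cycle_index[j]
    }
  }
  hits$quadrant <- quadrant
  hits$cycle_index <- cycle_index
  structure(hits, off_cycle = sum(is.na(quadrant)))
}
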
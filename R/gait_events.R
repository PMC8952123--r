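# Heel-strike detection and gait-cycle segmentation.

# Zero-phase filtering with odd-reflection end padding, which suppresses
# the start/end transients of plain filtfilt (zero initial conditions).
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  L <- min(n - 1L, 3L * (max(length(bf$b), length(bf$a)) - 1L) * 4L)
  if (L < 1L) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(L + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - L)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(L + 1L):(L + n)]
}
#
# One gait cycle spans two consecutive heel strikes of the same foot. The
# heel-strike impact produces a sharp peak in the vertical acceleration of
# the heel marker, which is what the detector looks for after low-pass
# filtering the position signal.

#' Detect heel strikes from a heel-marker trajectory
#'
#' The vertical component of the heel position is zero-phase low-pass
#' filtered (Butterworth, `order`, `cutoff_hz`), its acceleration computed
#' by central differences, and heel strikes placed at local acceleration
#' maxima that exceed an adaptive threshold (mean + `threshold_k` SD of the
#' acceleration) and are separated by at least `min_separation_s`. When
#' candidate peaks fall closer than the refractory interval the larger one
#' wins.
#'
#' @param heel numeric `frames x 3` matrix in mm; gaps must be filled.
#' @param rate sampling frequency in Hz (>= 20 so the filter is usable).
#' @param vertical_axis column index of the vertical axis (default 2, +Y up).
#' @param cutoff_hz low-pass cutoff, default 6 Hz.
#' @param order Butterworth order, default 4.
#' @param threshold_k SD multiplier of the adaptive threshold, default 1.
#' @param min_separation_s refractory period between events, default 0.5 s.
#' @return integer vector of 1-based heel-strike frame indices (possibly
#'   empty, with a warning).
#' @export
detect_heel_strikes <- function(heel, rate, vertical_axis = 2L,
                                cutoff_hz = 6, order = 4L,
                                threshold_k = 1, min_separation_s = 0.5) {
  heel <- as.matrix(heel)
  if (rate < 20)
    stop("sampling rate too low for heel-strike filtering (< 20 Hz)",
         call. = FALSE)
  if (nrow(heel) < rate)
    stop("need at least 1 s of heel data", call. = FALSE)
  y <- heel[, vertical_axis]
  if (anyNA(y))
    stop("heel trajectory contains gaps; fill them first", call. = FALSE)

  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  yf <- filtfilt_padded(bf, y - mean(y))
  n <- length(yf)
  acc <- rep(NA_real_, n)
  acc[2:(n - 1)] <- (yf[3:n] - 2 * yf[2:(n - 1)] + yf[1:(n - 2)]) * rate^2
  a <- acc[2:(n - 1)]
  thr <- mean(a) + threshold_k * stats::sd(a)

  is_peak <- which(a > c(-Inf, a[-length(a)]) &
                   a >= c(a[-1], -Inf) & a > thr) + 1L
  if (!length(is_peak)) {
    warning("no heel strikes detected")
    return(integer())
  }
  # enforce the refractory period, keeping the stronger peak
  min_gap <- round(min_separation_s * rate)
  keep <- integer()
  for (p in is_peak[order(acc[is_peak], decreasing = TRUE)]) {
    if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Gait sub-phase intervals on the normalized cycle axis
#'
#' Fixed percentages of the gait cycle: flat foot is reached at 10%,
#' heel off at 50%, toe off at 73% and the next heel strike at 100%.
#'
#' @return named list of `c(from, to)` percentage intervals partitioning
#'   0-100.
#' @export
subphase_indices <- function() {
  list(flat_foot = c(0, 10),
       heel_off = c(10, 50),
       toe_off = c(50, 73),
       heel_strike = c(73, 100))
}

#' Set of time-normalized gait cycles
#'
#' @param events ordered heel-strike frame indices.
#' @param cycles numeric `n_cycles x 101 x 3` array (columns rotx, roty,
#'   rotz in degrees), each cycle resampled to 0-100% of the gait cycle.
#' @param excluded data.frame with columns `cycle` and `reason` for
#'   dropped cycles.
#' @param rate Hz.
#' @return an object of class `gait_cycle_set`.
#' @export
gait_cycle_set <- function(events, cycles, excluded, rate) {
  stopifnot(length(dim(cycles)) == 3L, dim(cycles)[2] == 101L,
            dim(cycles)[3] == 3L)
  if (is.unsorted(events, strictly = TRUE))
    stop("events must be strictly increasing", call. = FALSE)
  structure(list(events = as.integer(events), cycles = cycles,
                 excluded = excluded, rate = as.numeric(rate)),
            class = "gait_cycle_set")
}

#' @export
print.gait_cycle_set <- function(x, ...) {
  cat(sprintf("<gait_cycle_set> %d events, %d kept cycles, %d excluded\n",
              length(x$events), dim(x$cycles)[1], nrow(x$excluded)))
  invisible(x)
}

#' Segment an angle series into time-normalized gait cycles
#'
#' Forms one cycle per consecutive heel-strike pair, excludes the first and
#' last cycle (gait acceleration/deceleration makes them unstable), drops
#' any cycle containing invalid angle frames, and linearly resamples each
#' kept cycle to 101 points on the 0-100% axis so that the sub-phase
#' percentages (10, 50, 73, 100) index exact samples.
#'
#' @param angles a [relative_angle_series].
#' @param events heel-strike frame indices from [detect_heel_strikes].
#' @return a [gait_cycle_set].
#' @export
segment_cycles <- function(angles, events) {
  stopifnot(inherits(angles, "relative_angle_series"))
  if (length(events) < 4L)
    stop("need at least 4 heel strikes (3 raw cycles) so that at least ",
         "one cycle survives first/last exclusion; got ", length(events),
         call. = FALSE)
  n_raw <- length(events) - 1L
  sig <- cbind(angles$rotx, angles$roty, angles$rotz)
  kept <- list()
  excluded <- data.frame(cycle = integer(), reason = character())
  for (ci in seq_len(n_raw)) {
    if (ci == 1L || ci == n_raw) {
      excluded <- rbind(excluded, data.frame(
        cycle = ci, reason = if (ci == 1L) "first cycle" else "last cycle"))
      next
    }
    f0 <- events[ci]; f1 <- events[ci + 1L]
    idx <- f0:f1
    if (any(!angles$valid[idx])) {
      excluded <- rbind(excluded,
                        data.frame(cycle = ci, reason = "invalid frames"))
      next
    }
    kept[[length(kept) + 1L]] <- normalize_cycle(sig[idx, , drop = FALSE])
  }
  cycles <- array(NA_real_, c(length(kept), 101L, 3L))
  for (i in seq_along(kept)) cycles[i, , ] <- kept[[i]]
  gait_cycle_set(events, cycles, excluded, angles$rate)
}

# linear resampling of one raw cycle (frames x 3) onto 0..100%
normalize_cycle <- function(raw) {
  n <- nrow(raw)
  x_old <- seq(0, 100, length.out = n)
  x_new <- 0:100
  vapply(1:3, function(k)
    stats::approx(x_old, raw[, k], xout = x_new)$y, numeric(101L))
}

#' Export kept cycles to CSV
#'
#' Columns `cycle,percent,rotx_deg,roty_deg,rotz_deg`, one row per cycle
#' and percentage point.
#'
#' @param cs a [gait_cycle_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cs, path) {
  stopifnot(inherits(cs, "gait_cycle_set"))
  nc <- dim(cs$cycles)[1]
  df <- do.call(rbind, lapply(seq_len(nc), function(i)
    data.frame(cycle = i, percent = 0:100,
               rotx_deg = cs$cycles[i, , 1],
               roty_deg = cs$cycles[i, , 2],
               rotz_deg = cs$cycles[i, , 3])))
  if (is.null(df))
    df <- data.frame(cycle = integer(), percent = integer(),
                     rotx_deg = numeric(), roty_deg = numeric(),
                     rotz_deg = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export detected events to JSON
#'
#' @param events heel-strike frame indices.
#' @param rate Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, rate, path) {
  jsonlite::write_json(
    list(frames = as.integer(events), times_s = (events - 1) / rate),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
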
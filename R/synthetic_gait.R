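# Synthetic walking trials with known ground truth.
#
# Generates marker trajectories of a thigh oscillating in the sagittal
# plane with an exoskeleton link attached through a prescribed relative
# rotation (constant offset plus sinusoidal slippage per axis), a heel
# marker with impact-like decelerations at planted stride boundaries,
# isotropic marker noise and configurable gaps. Every downstream module is
# validated against the exact truth carried alongside.
#
# Conventions: global +Y is up, +Z points laterally (right), +X is the
# walking direction. Units mm, degrees, seconds.

#' Configuration for a synthetic walking trial
#'
#' Defaults emulate the structure of an instrumented 6-m walking trial:
#' 100 Hz sampling, a 45 cm femur (mid-range of typical adult
#' anthropometry), a cadence of 0.91 strides/s (1.1 s stride period), a
#' sagittal thigh oscillation of 20 degrees, a dominant sagittal
#' misalignment offset of 30 degrees with a few degrees of sinusoidal
#' slippage, and 0.5 mm marker noise (optical capture accuracy is an order
#' of magnitude better; 0.5 mm stands in for residual soft-tissue and
#' labeling jitter).
#'
#' @param seed integer; fixes all randomness.
#' @param rate sampling frequency, Hz.
#' @param duration trial length, s.
#' @param cadence strides per second (one stride = one gait cycle).
#' @param thigh_amplitude,thigh_offset sagittal thigh oscillation, degrees.
#' @param offset named `c(rotx=, roty=, rotz=)` constant relative
#'   misalignment, degrees.
#' @param slip_amplitude named per-axis sinusoidal slippage amplitude,
#'   degrees.
#' @param slip_phase named per-axis slippage phase, radians.
#' @param noise_sd isotropic marker noise SD, mm.
#' @param gap_spec list of `list(marker=, start=, length=)` gap insertions
#'   (frames, 1-based).
#' @param femur_length_mm thigh segment length, mm.
#' @param heel_lift_mm smooth heel oscillation amplitude, mm.
#' @param impact_depth_mm,impact_width_s Gaussian heel-impact dip depth and
#'   temporal width; these create the sharp vertical deceleration the event
#'   detector keys on.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, rate = 100, duration = 12,
                             cadence = 1 / 1.1,
                             thigh_amplitude = 20, thigh_offset = 10,
                             offset = c(rotx = -0.7, roty = 1.1, rotz = 30),
                             slip_amplitude = c(rotx = 3.5, roty = 2.2,
                                                rotz = 3.4),
                             slip_phase = c(rotx = 0.6, roty = 2.1,
                                            rotz = 0),
                             noise_sd = 0.5,
                             gap_spec = list(),
                             femur_length_mm = 450,
                             heel_lift_mm = 30,
                             impact_depth_mm = 10,
                             impact_width_s = 0.05) {
  stopifnot(rate > 0, duration > 0, cadence > 0, noise_sd >= 0)
  offset <- complete_axes(offset)
  slip_amplitude <- complete_axes(slip_amplitude)
  slip_phase <- complete_axes(slip_phase)
  structure(as.list(environment()), class = "synthetic_config")
}

complete_axes <- function(v) {
  out <- c(rotx = 0, roty = 0, rotz = 0)
  out[names(v)] <- v
  out
}

# marker positions in the local frame of each body (origin at the distal
# reference point / knee), mm
THIGH_LOCALS <- list(EPSD = c(0, 400, 50), EASD = c(0, 400, -50),
                     CMD = c(0, 0, -55), CLD = c(0, 0, 55))
EXO_LOCALS <- list(exoHR = c(0, 400, 0), exoKR = c(0, 0, 0),
                   R3 = c(0, 300, 60), R4 = c(75, 150, 60),
                   R5 = c(-75, 150, 60))

#' Simulate one synthetic walking trial
#'
#' Builds the thigh frame as a sagittal rotation (about global Z) at the
#' configured cadence, attaches the anatomical markers at fixed body-frame
#' positions, composes the exoskeleton frame as the thigh frame times the
#' prescribed relative rotation (intrinsic ZXY of the offset plus
#' sinusoidal slippage), attaches the device markers, synthesizes a heel
#' trajectory whose filtered vertical acceleration peaks exactly at the
#' planted stride boundaries, then adds Gaussian marker noise and inserts
#' the configured gaps.
#'
#' @param cfg a [synthetic_config].
#' @return list with `trajectories` (a [marker_trajectory_set]) and
#'   `truth` (class `synthetic_truth`: `$angles` the exact
#'   [relative_angle_series], `$events` planted heel-strike frames,
#'   `$clean` the noiseless [marker_trajectory_set]).
#' @export
simulate_trial <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$rate)
  tt <- (seq_len(n) - 1) / cfg$rate
  period <- 1 / cfg$cadence
  t0 <- 0.3 * period                      # first strike off the trial edge

  # planted heel-strike times/frames
  ev_times <- seq(t0, cfg$duration - 1 / cfg$rate, by = period)
  ev_frames <- round(ev_times * cfg$rate) + 1L

  # prescribed signals
  phase <- 2 * pi * (tt - t0) / period
  thigh_deg <- cfg$thigh_offset + cfg$thigh_amplitude * sin(phase)
  ax <- cfg$offset[["rotx"]] + cfg$slip_amplitude[["rotx"]] *
    sin(phase + cfg$slip_phase[["rotx"]])
  ay <- cfg$offset[["roty"]] + cfg$slip_amplitude[["roty"]] *
    sin(phase + cfg$slip_phase[["roty"]])
  az <- cfg$offset[["rotz"]] + cfg$slip_amplitude[["rotz"]] *
    sin(phase + cfg$slip_phase[["rotz"]])

  labels <- c(names(THIGH_LOCALS), names(EXO_LOCALS), "HEEL")
  pos <- array(NA_real_, c(n, length(labels), 3L))
  hip <- c(0, 900, 0)
  for (i in seq_len(n)) {
    R_th <- axis_rotation("Z", thigh_deg[i] * pi / 180)
    knee <- hip + R_th %*% c(0, -cfg$femur_length_mm, 0)
    R_rel <- compose_euler(ax[i], ay[i], az[i], "ZXY")
    R_exo <- R_rel %*% R_th
    for (mk in names(THIGH_LOCALS))
      pos[i, match(mk, labels), ] <- knee + R_th %*% THIGH_LOCALS[[mk]]
    for (mk in names(EXO_LOCALS))
      pos[i, match(mk, labels), ] <- knee + R_exo %*% EXO_LOCALS[[mk]]
  }

  # heel: forward progression, smooth stride lift, Gaussian impact dips
  stride_len <- 1200
  heel_x <- stride_len * tt / period
  heel_y <- cfg$heel_lift_mm * (1 - cos(2 * pi * (tt - t0) / period)) / 2
  for (te in ev_times)
    heel_y <- heel_y - cfg$impact_depth_mm *
      exp(-(tt - te)^2 / (2 * cfg$impact_width_s^2))
  pos[, match("HEEL", labels), 1] <- heel_x
  pos[, match("HEEL", labels), 2] <- heel_y
  pos[, match("HEEL", labels), 3] <- 200

  clean <- marker_trajectory_set(labels, pos, cfg$rate,
                                 source = sprintf("synthetic seed=%d (clean)",
                                                  cfg$seed))
  if (cfg$noise_sd > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, cfg$noise_sd), dim(pos))

  gap <- matrix(FALSE, n, length(labels))
  for (g in cfg$gap_spec) {
    j <- match(g$marker, labels)
    if (is.na(j)) stop("gap_spec names unknown marker: ", g$marker,
                       call. = FALSE)
    idx <- g$start:(g$start + g$length - 1L)
    if (any(idx < 1L) || any(idx > n))
      stop("gap_spec exceeds trial length for marker ", g$marker,
           call. = FALSE)
    gap[idx, j] <- TRUE
  }

  truth <- structure(list(
    angles = relative_angle_series(ax, ay, az, cfg$rate, rep(TRUE, n),
                                   convention = "ZXY"),
    events = ev_frames,
    clean = clean), class = "synthetic_truth")

  list(trajectories = marker_trajectory_set(
         labels, pos, cfg$rate, gap,
         source = sprintf("synthetic seed=%d noise=%.3gmm", cfg$seed,
                          cfg$noise_sd)),
       truth = truth)
}

#' Write a trajectory fixture to disk
#'
#' @param t a [marker_trajectory_set].
#' @param path output path.
#' @param format `"c3d"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(t, path, format = c("c3d", "csv")) {
  format <- match.arg(format)
  switch(format,
         c3d = write_c3d(t, path),
         csv = write_csv_trajectories(t, path))
}

#' Read a synthetic configuration from YAML/JSON
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#' @param path config file.
#' @return a [synthetic_config].
#' @export
read_synthetic_config <- function(path) {
  cfg <- read_config(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown synthetic config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in c("offset", "slip_amplitude", "slip_phase"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  do.call(synthetic_config, cfg)
}
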
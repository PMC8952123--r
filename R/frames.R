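# Segment coordinate frames and relative orientation.
#
# The method expresses the thigh and the exoskeleton link as orthonormal
# local frames built from markers, then measures the device-vs-limb
# misalignment as the rotation R_exo/th = R_exo/O %*% t(R_th/O), decomposed
# into three anatomical-plane angles (RotZ sagittal, RotX frontal,
# RotY transverse).

#' Per-frame rotation-matrix series
#'
#' @param rotations numeric `frames x 3 x 3` array; for each valid frame the
#'   3x3 slice is an orthonormal rotation whose columns are the body X, Y, Z
#'   unit axes expressed in the global frame.
#' @param valid logical per-frame validity (FALSE where a defining marker was
#'   in a gap or the geometry was degenerate).
#' @param body one of `"thigh"`, `"exo"`, `"relative"`.
#' @param rate sampling frequency in Hz.
#' @param reasons optional character vector of per-frame invalidity reasons.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(rotations, valid, body, rate, reasons = NULL) {
  body <- match.arg(body, c("thigh", "exo", "relative"))
  stopifnot(length(dim(rotations)) == 3L,
            dim(rotations)[2] == 3L, dim(rotations)[3] == 3L,
            length(valid) == dim(rotations)[1])
  structure(list(rotations = rotations, valid = as.logical(valid),
                 body = body, rate = as.numeric(rate),
                 reasons = reasons),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> body=%s, %d frames @ %g Hz, %d valid\n",
              x$body, length(x$valid), x$rate, sum(x$valid)))
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v * v))
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Build one orthonormal, right-handed frame anchored on the longitudinal
# axis y. x = y x z re-derives the anteroposterior axis, then z = x x y
# restores exact orthogonality; y is kept verbatim because the longitudinal
# axis is the anatomically anchored one and marker noise should perturb the
# mediolateral axis, not it.
orthonormal_frame <- function(y_raw, z_raw, tol = 1e-6) {
  ny <- vnorm(y_raw)
  nz <- vnorm(z_raw)
  if (!is.finite(ny) || !is.finite(nz) || ny < tol || nz < tol)
    return(NULL)
  y <- y_raw / ny
  x_raw <- vcross(y, z_raw / nz)
  nx <- vnorm(x_raw)
  if (nx < tol) return(NULL)                     # y parallel to z
  x <- x_raw / nx
  z <- vcross(x, y)
  cbind(x, y, z, deparse.level = 0)
}

#' Thigh local frame from anatomical markers
#'
#' Per frame: the proximal reference is the midpoint of EPSD and EASD, the
#' distal reference the midpoint of CMD and CLD (between the femoral
#' condyles). The longitudinal axis y runs distal-to-proximal, the
#' mediolateral axis z from the distal midpoint to the lateral condyle CLD,
#' and the anteroposterior axis x = y x z points forward. The frame is
#' re-orthogonalized keeping y exact.
#'
#' Frames where any of the four markers is in a gap, or where the marker
#' geometry degenerates (zero-length or parallel axes), are marked invalid
#' rather than raising an error.
#'
#' @param t a [marker_trajectory_set].
#' @param m a [marker_map].
#' @return a [frame_series] with `body = "thigh"`.
#' @export
thigh_frame <- function(t, m = default_marker_map()) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  check_markers_present(t, m, c("EPSD", "EASD", "CMD", "CLD"))
  epsd <- marker_xyz(t, m[["EPSD"]]); easd <- marker_xyz(t, m[["EASD"]])
  cmd <- marker_xyz(t, m[["CMD"]]);  cld <- marker_xyz(t, m[["CLD"]])
  n <- n_frames(t)
  rot <- array(NA_real_, c(n, 3L, 3L))
  valid <- rep(FALSE, n)
  reasons <- rep(NA_character_, n)
  gap <- t$gap_mask[, match(unlist(m[c("EPSD", "EASD", "CMD", "CLD")]),
                            t$labels), drop = FALSE]
  for (i in seq_len(n)) {
    if (any(gap[i, ])) { reasons[i] <- "marker gap"; next }
    t_up <- (epsd[i, ] + easd[i, ]) / 2
    t_low <- (cmd[i, ] + cld[i, ]) / 2
    R <- orthonormal_frame(t_up - t_low, cld[i, ] - t_low)
    if (is.null(R)) { reasons[i] <- "degenerate geometry"; next }
    rot[i, , ] <- R
    valid[i] <- TRUE
  }
  frame_series(rot, valid, "thigh", t$rate, reasons)
}

#' Exoskeleton-link local frame from device markers
#'
#' Per frame: the longitudinal axis y runs from the knee motor marker exoKR
#' up to the hip motor marker exoHR; the mediolateral axis z is the normal
#' of the plane spanned by the link cluster (R3, R4, R5), sign-corrected to
#' point laterally; the anteroposterior axis x = y x z. Re-orthogonalized
#' keeping y exact.
#'
#' The cluster cross product's sign depends on arbitrary marker ordering, so
#' z is flipped when it disagrees with the thigh mediolateral axis of the
#' same frame (when `thigh` is supplied and valid there); without a thigh
#' reference the sign making the first valid frame's z point toward global
#' +Z is applied throughout.
#'
#' @param t a [marker_trajectory_set].
#' @param m a [marker_map].
#' @param thigh optional thigh [frame_series] used for the lateral
#'   sign correction.
#' @return a [frame_series] with `body = "exo"`.
#' @export
exo_frame <- function(t, m = default_marker_map(), thigh = NULL) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  check_markers_present(t, m, c("exoHR", "exoKR", "R3", "R4", "R5"))
  hr <- marker_xyz(t, m[["exoHR"]]); kr <- marker_xyz(t, m[["exoKR"]])
  r3 <- marker_xyz(t, m[["R3"]]); r4 <- marker_xyz(t, m[["R4"]])
  r5 <- marker_xyz(t, m[["R5"]])
  n <- n_frames(t)
  rot <- array(NA_real_, c(n, 3L, 3L))
  valid <- rep(FALSE, n)
  reasons <- rep(NA_character_, n)
  gap <- t$gap_mask[, match(unlist(m[c("exoHR", "exoKR", "R3", "R4", "R5")]),
                            t$labels), drop = FALSE]

  # decide the fallback global sign from the first constructible frame
  fallback_flip <- NULL
  for (i in seq_len(n)) {
    if (any(gap[i, ])) { reasons[i] <- "marker gap"; next }
    z_raw <- vcross(r3[i, ] - r4[i, ], r3[i, ] - r5[i, ])
    R <- orthonormal_frame(hr[i, ] - kr[i, ], z_raw)
    if (is.null(R)) { reasons[i] <- "degenerate geometry"; next }
    flip <- NA
    if (!is.null(thigh) && thigh$valid[i]) {
      flip <- sum(R[, 3] * thigh$rotations[i, , 3]) < 0
    } else {
      if (is.null(fallback_flip)) fallback_flip <- R[3, 3] < 0
      flip <- fallback_flip
    }
    if (isTRUE(flip)) { R[, 3] <- -R[, 3]; R[, 1] <- -R[, 1] }
    rot[i, , ] <- R
    valid[i] <- TRUE
  }
  frame_series(rot, valid, "exo", t$rate, reasons)
}

#' Relative rotation of the exoskeleton link with respect to the thigh
#'
#' Per frame, `R_rel = R_exo %*% t(R_thigh)`; the transpose is the exact
#' inverse because both inputs are orthonormal. Valid only where both
#' inputs are valid.
#'
#' @param exo exoskeleton [frame_series].
#' @param th thigh [frame_series].
#' @return a [frame_series] with `body = "relative"`.
#' @export
relative_rotation <- function(exo, th) {
  stopifnot(inherits(exo, "frame_series"), inherits(th, "frame_series"))
  n <- length(exo$valid)
  if (length(th$valid) != n)
    stop("frame series lengths differ (", n, " vs ", length(th$valid), ")",
         call. = FALSE)
  if (!isTRUE(all.equal(exo$rate, th$rate)))
    stop("frame series rates differ", call. = FALSE)
  rot <- array(NA_real_, c(n, 3L, 3L))
  valid <- exo$valid & th$valid
  for (i in which(valid))
    rot[i, , ] <- exo$rotations[i, , ] %*% t(th$rotations[i, , ])
  frame_series(rot, valid, "relative", exo$rate)
}

EULER_CONVENTIONS <- c("ZXY", "XYZ", "ZYX")

axis_rotation <- function(axis, angle_rad) {
  c <- cos(angle_rad); s <- sin(angle_rad)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    Y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    Z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

#' Compose a rotation matrix from per-axis angles
#'
#' Builds the rotation corresponding to an intrinsic Euler sequence from
#' angles given per body axis. The default `"ZXY"` sequence applies the
#' sagittal rotation first, then frontal, then transverse.
#'
#' @param rotx,roty,rotz angles in degrees about the X (anteroposterior),
#'   Y (longitudinal) and Z (mediolateral) axes.
#' @param convention `"ZXY"` (default), `"XYZ"` or `"ZYX"`.
#' @return a 3x3 rotation matrix.
#' @export
compose_euler <- function(rotx, roty, rotz, convention = "ZXY") {
  convention <- match.arg(convention, EULER_CONVENTIONS)
  ang <- c(X = rotx, Y = roty, Z = rotz) * pi / 180
  axes <- strsplit(convention, "")[[1]]
  axis_rotation(axes[1], ang[[axes[1]]]) %*%
    axis_rotation(axes[2], ang[[axes[2]]]) %*%
    axis_rotation(axes[3], ang[[axes[3]]])
}

decompose_one <- function(R, convention) {
  r <- function(i, j) R[i, j]
  switch(convention,
    ZXY = {
      sx <- max(-1, min(1, r(3, 2)))
      lock <- abs(sx) > 1 - 1e-9
      if (lock) {
        # middle angle at +/-90 deg: only the sum/difference of the outer
        # angles is defined; assign it all to rotz
        x <- asin(sx)
        z <- atan2(sign(sx) * r(1, 3), r(1, 1))
        y <- 0
      } else {
        x <- asin(sx)
        z <- atan2(-r(1, 2), r(2, 2))
        y <- atan2(-r(3, 1), r(3, 3))
      }
      list(x = x, y = y, z = z, lock = lock)
    },
    XYZ = {
      sy <- max(-1, min(1, r(1, 3)))
      lock <- abs(sy) > 1 - 1e-9
      if (lock) {
        y <- asin(sy)
        x <- atan2(sign(sy) * r(2, 1), r(2, 2))
        z <- 0
      } else {
        y <- asin(sy)
        x <- atan2(-r(2, 3), r(3, 3))
        z <- atan2(-r(1, 2), r(1, 1))
      }
      list(x = x, y = y, z = z, lock = lock)
    },
    ZYX = {
      sy <- max(-1, min(1, -r(3, 1)))
      lock <- abs(sy) > 1 - 1e-9
      if (lock) {
        y <- asin(sy)
        z <- atan2(-sign(sy) * r(1, 2), r(2, 2))
        x <- 0
      } else {
        y <- asin(sy)
        z <- atan2(r(2, 1), r(1, 1))
        x <- atan2(r(3, 2), r(3, 3))
      }
      list(x = x, y = y, z = z, lock = lock)
    })
}

#' Relative angle series
#'
#' @param rotx,roty,rotz per-frame angles in degrees.
#' @param rate Hz.
#' @param valid logical per-frame validity.
#' @param convention Euler sequence identifier.
#' @param gimbal_lock integer indices of frames decomposed at the
#'   gimbal-lock degeneracy.
#' @return an object of class `relative_angle_series`.
#' @export
relative_angle_series <- function(rotx, roty, rotz, rate, valid,
                                  convention = "ZXY",
                                  gimbal_lock = integer()) {
  structure(list(rotx = rotx, roty = roty, rotz = rotz,
                 rate = as.numeric(rate), valid = as.logical(valid),
                 convention = convention, gimbal_lock = gimbal_lock),
            class = "relative_angle_series")
}

#' @export
print.relative_angle_series <- function(x, ...) {
  cat(sprintf(
    "<relative_angle_series> %d frames @ %g Hz (%s), %d valid\n",
    length(x$valid), x$rate, x$convention, sum(x$valid)))
  invisible(x)
}

#' Euler decomposition of a relative rotation series
#'
#' Decomposes each valid relative rotation into three anatomical-plane
#' angles in degrees: RotZ (sagittal), RotX (frontal), RotY (transverse).
#' The default intrinsic `"ZXY"` sequence extracts the dominant sagittal
#' rotation first, minimizing cross-talk into the small frontal and
#' transverse angles. Invalid frames carry `NA`. Frames within 1e-9 of the
#' gimbal-lock degeneracy (|middle angle| = 90 deg) are decomposed by the
#' standard convention (third angle set to zero) and listed in
#' `$gimbal_lock`.
#'
#' @param rel a [frame_series] with `body = "relative"`.
#' @param convention `"ZXY"` (default), `"XYZ"` or `"ZYX"`.
#' @return a [relative_angle_series].
#' @export
euler_angles <- function(rel, convention = "ZXY") {
  stopifnot(inherits(rel, "frame_series"))
  if (rel$body != "relative")
    stop("euler_angles expects a relative frame series", call. = FALSE)
  convention <- match.arg(convention, EULER_CONVENTIONS)
  n <- length(rel$valid)
  rotx <- roty <- rotz <- rep(NA_real_, n)
  lock <- integer()
  for (i in which(rel$valid)) {
    d <- decompose_one(rel$rotations[i, , ], convention)
    rotx[i] <- d$x * 180 / pi
    roty[i] <- d$y * 180 / pi
    rotz[i] <- d$z * 180 / pi
    if (d$lock) lock <- c(lock, i)
  }
  relative_angle_series(rotx, roty, rotz, rel$rate, rel$valid,
                        convention, lock)
}

#' Export an angle series to CSV
#'
#' Columns: `frame` (0-based), `time_s`, `rotx_deg`, `roty_deg`,
#' `rotz_deg`, `valid`.
#'
#' @param a a [relative_angle_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(a, path) {
  stopifnot(inherits(a, "relative_angle_series"))
  n <- length(a$valid)
  df <- data.frame(frame = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / a$rate,
                   rotx_deg = a$rotx, roty_deg = a$roty, rotz_deg = a$rotz,
                   valid = a$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
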
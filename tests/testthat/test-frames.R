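# Segment frame construction, relative rotation and Euler decomposition.

make_single_pose <- function(markers, rate = 100) {
  # duplicate one pose over 2 frames (minimum trajectory length)
  pos <- array(NA_real_, c(2, length(markers), 3L))
  for (j in seq_along(markers)) for (i in 1:2) pos[i, j, ] <- markers[[j]]
  marker_trajectory_set(names(markers), pos, rate)
}

test_that("thigh frame follows the midpoint construction", {
  # t_up = midpoint(EPSD, EASD), t_low = midpoint(CMD, CLD), y = t_up - t_low
  mk <- ref_constellation()
  mk$EPSD <- c(10, 100, 10); mk$EASD <- c(-10, 100, 10)
  mk$CMD <- c(-10, 0, 10);   mk$CLD <- c(10, 0, -10)
  t <- make_single_pose(mk)
  fs <- thigh_frame(t)
  y_raw <- c(0, 100, 10) - c(0, 0, 0)
  expect_true(fs$valid[1])
  # the longitudinal axis is kept verbatim (unit-normalized)
  expect_equal(fs$rotations[1, , 2], y_raw / sqrt(sum(y_raw^2)),
               tolerance = 1e-12)
})

test_that("orthonormal marker geometry yields the identity frame", {
  mk <- ref_constellation()   # y = (0,400,0), z_raw = (0,0,40): axis-aligned
  t <- make_single_pose(mk)
  fs <- thigh_frame(t)
  expect_equal(fs$rotations[1, , ], diag(3), tolerance = 1e-12)
})

test_that("thigh and exo frames recover applied rotations to 1e-9", {
  set.seed(42)
  rots <- replicate(50, rand_rotation(), simplify = FALSE)
  t <- posed_trajectories(rots)
  th <- thigh_frame(t)
  ex <- exo_frame(t, thigh = th)
  for (i in seq_along(rots)) {
    expect_lt(max(abs(th$rotations[i, , ] - rots[[i]])), 1e-9)
    expect_lt(max(abs(ex$rotations[i, , ] - rots[[i]])), 1e-9)
    for (fs in list(th, ex)) {
      R <- fs$rotations[i, , ]
      expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-9)
      expect_lt(abs(det(R) - 1), 1e-9)
    }
  }
})

test_that("frames are equivariant under a global rotation", {
  set.seed(7)
  G <- rand_rotation()
  rots <- replicate(5, rand_rotation(), simplify = FALSE)
  t1 <- posed_trajectories(rots)
  t2 <- posed_trajectories(lapply(rots, function(R) G %*% R))
  th1 <- thigh_frame(t1); th2 <- thigh_frame(t2)
  ex1 <- exo_frame(t1, thigh = th1); ex2 <- exo_frame(t2, thigh = th2)
  for (i in seq_along(rots)) {
    expect_equal(th2$rotations[i, , ], G %*% th1$rotations[i, , ],
                 tolerance = 1e-9)
    expect_equal(ex2$rotations[i, , ], G %*% ex1$rotations[i, , ],
                 tolerance = 1e-9)
  }
  r1 <- relative_rotation(ex1, th1)
  r2 <- relative_rotation(ex2, th2)
  expect_equal(r1$rotations, r2$rotations, tolerance = 1e-9)
})

test_that("exo frame geometry matches the motor-axis construction", {
  mk <- ref_constellation()
  fs <- exo_frame(make_single_pose(mk))
  # longitudinal axis along exoHR - exoKR = (0,400,0)
  expect_equal(fs$rotations[1, , 2], c(0, 1, 0), tolerance = 1e-12)
  # cluster plane has constant z: mediolateral axis is +/- global Z,
  # sign-corrected to +Z (first-frame fallback)
  expect_equal(abs(fs$rotations[1, , 3]), c(0, 0, 1), tolerance = 1e-12)
  expect_gt(fs$rotations[1, 3, 3], 0)
})

test_that("degenerate marker geometry invalidates frames without error", {
  mk <- ref_constellation()
  mk$R4 <- mk$R3                      # collinear cluster
  fs <- exo_frame(make_single_pose(mk))
  expect_false(any(fs$valid))
  expect_match(fs$reasons[1], "degenerate")

  mk2 <- ref_constellation()
  mk2$EPSD <- mk2$EASD <- c(0, 0, 60) # y parallel to z
  mk2$CMD <- c(0, 0, -40); mk2$CLD <- c(0, 0, 40)
  fs2 <- thigh_frame(make_single_pose(mk2))
  expect_false(any(fs2$valid))
})

test_that("marker gaps invalidate exactly the affected frames", {
  set.seed(3)
  rots <- replicate(6, rand_rotation(), simplify = FALSE)
  t <- posed_trajectories(rots)
  gap <- matrix(FALSE, 6, length(t$labels))
  gap[3, match("CMD", t$labels)] <- TRUE
  gap[5, match("R5", t$labels)] <- TRUE
  tg <- marker_trajectory_set(t$labels, t$positions, t$rate, gap)
  th <- thigh_frame(tg); ex <- exo_frame(tg, thigh = th)
  expect_identical(th$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(ex$valid, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  rel <- relative_rotation(ex, th)
  expect_identical(rel$valid, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  ang <- euler_angles(rel)
  expect_true(all(is.na(ang$rotx[!rel$valid])))
  expect_true(all(is.finite(ang$rotx[rel$valid])))
})

test_that("relative rotation matches an explicit-inverse oracle", {
  set.seed(99)
  n <- 1000
  rot_e <- array(NA_real_, c(n, 3, 3))
  rot_t <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    rot_e[i, , ] <- rand_rotation()
    rot_t[i, , ] <- rand_rotation()
  }
  ex <- frame_series(rot_e, rep(TRUE, n), "exo", 100)
  th <- frame_series(rot_t, rep(TRUE, n), "thigh", 100)
  rel <- relative_rotation(ex, th)
  worst <- 0
  for (i in seq_len(n)) {
    oracle <- rot_e[i, , ] %*% solve(rot_t[i, , ])   # general matrix inverse
    worst <- max(worst, max(abs(rel$rotations[i, , ] - oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("relative_rotation(F, F) is the identity with zero angles", {
  set.seed(5)
  rot <- array(NA_real_, c(4, 3, 3))
  for (i in 1:4) rot[i, , ] <- rand_rotation()
  f_exo <- frame_series(rot, rep(TRUE, 4), "exo", 100)
  f_th <- frame_series(rot, rep(TRUE, 4), "thigh", 100)
  rel <- relative_rotation(f_exo, f_th)
  for (i in 1:4)
    expect_equal(rel$rotations[i, , ], diag(3), tolerance = 1e-12)
  ang <- euler_angles(rel)
  expect_equal(ang$rotx, rep(0, 4), tolerance = 1e-9)
  expect_equal(ang$roty, rep(0, 4), tolerance = 1e-9)
  expect_equal(ang$rotz, rep(0, 4), tolerance = 1e-9)
})

test_that("relative_rotation rejects mismatched series", {
  rot <- array(rep(diag(3), 2), c(2, 3, 3))
  for (i in 1:2) rot[i, , ] <- diag(3)
  a <- frame_series(rot, c(TRUE, TRUE), "exo", 100)
  b <- frame_series(rot[1, , , drop = FALSE], TRUE, "thigh", 100)
  expect_error(relative_rotation(a, b), "lengths differ")
})

test_that("single-axis rotations decompose to the expected angle", {
  rot <- array(NA_real_, c(3, 3, 3))
  rot[1, , ] <- compose_euler(0, 0, 30)
  rot[2, , ] <- compose_euler(12, 0, 0)
  rot[3, , ] <- compose_euler(0, -25, 0)
  rel <- frame_series(rot, rep(TRUE, 3), "relative", 100)
  a <- euler_angles(rel)
  expect_equal(a$rotz, c(30, 0, 0), tolerance = 1e-9)
  expect_equal(a$rotx, c(0, 12, 0), tolerance = 1e-9)
  expect_equal(a$roty, c(0, 0, -25), tolerance = 1e-9)
})

test_that("compose-then-decompose is the identity on small angles", {
  set.seed(123)
  for (conv in c("ZXY", "XYZ", "ZYX")) {
    n <- 500
    ang <- matrix(stats::runif(n * 3, -20, 20), ncol = 3)
    rot <- array(NA_real_, c(n, 3, 3))
    for (i in seq_len(n))
      rot[i, , ] <- compose_euler(ang[i, 1], ang[i, 2], ang[i, 3], conv)
    rel <- frame_series(rot, rep(TRUE, n), "relative", 100)
    d <- euler_angles(rel, conv)
    expect_lt(max(abs(cbind(d$rotx, d$roty, d$rotz) - ang)), 1e-9)
    expect_length(d$gimbal_lock, 0)
  }
})

test_that("gimbal lock is flagged and handled by convention", {
  rot <- array(NA_real_, c(2, 3, 3))
  rot[1, , ] <- compose_euler(90, 10, 20)       # middle (X) angle at 90
  rot[2, , ] <- compose_euler(5, 5, 5)
  rel <- frame_series(rot, c(TRUE, TRUE), "relative", 100)
  a <- euler_angles(rel, "ZXY")
  expect_identical(a$gimbal_lock, 1L)
  expect_equal(a$rotx[1], 90, tolerance = 1e-6)
  # the recomposed matrix must still match, even at the degeneracy
  expect_equal(compose_euler(a$rotx[1], a$roty[1], a$rotz[1]),
               rot[1, , ], tolerance = 1e-6)
})

test_that("angle CSV export has the documented columns", {
  rot <- array(NA_real_, c(2, 3, 3))
  rot[1, , ] <- compose_euler(1, 2, 3)
  rot[2, , ] <- compose_euler(2, 3, 4)
  a <- euler_angles(frame_series(rot, c(TRUE, TRUE), "relative", 100))
  p <- withr::local_tempfile(fileext = ".csv")
  write_angles_csv(a, p)
  df <- utils::read.csv(p)
  expect_identical(names(df), c("frame", "time_s", "rotx_deg", "roty_deg",
                                "rotz_deg", "valid"))
  expect_equal(df$frame, c(0, 1))
  expect_equal(df$rotz_deg, a$rotz, tolerance = 1e-6)
})
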
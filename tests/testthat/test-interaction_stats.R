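# Orientation-difference statistics against brute-force oracles.

test_that("overall_mean equals a flat brute-force average", {
  cs <- random_cycle_set(7, seed = 31)
  om <- overall_mean(cs)
  for (k in 1:3) {
    acc <- 0; cnt <- 0
    for (i in 1:7) for (p in 1:101) {
      acc <- acc + cs$cycles[i, p, k]
      cnt <- cnt + 1
    }
    expect_equal(unname(om[k]), acc / cnt, tolerance = 1e-12)
  }
  # constants behave like constants
  const <- array(38.15, c(3, 101, 3))
  expect_equal(unname(overall_mean(cycle_set_from_array(const))),
               rep(38.15, 3))
  two <- array(rep(c(4, 10), each = 1), c(2, 101, 3))
  two[1, , ] <- 4; two[2, , ] <- 10
  expect_equal(unname(overall_mean(cycle_set_from_array(two))), rep(7, 3))
})

test_that("range_stats matches a per-cycle max/min loop", {
  cs <- random_cycle_set(6, seed = 32)
  rs <- range_stats(cs)
  for (k in 1:3) {
    ranges <- numeric(6)
    for (i in 1:6) {
      lo <- Inf; hi <- -Inf
      for (p in 1:101) {
        v <- cs$cycles[i, p, k]
        lo <- min(lo, v); hi <- max(hi, v)
      }
      ranges[i] <- hi - lo
    }
    expect_equal(unname(rs$mean[k]), mean(ranges), tolerance = 1e-12)
    expect_equal(unname(rs$sd[k]), stats::sd(ranges), tolerance = 1e-12)
    expect_equal(unname(rs$cv[k]), 100 * stats::sd(ranges) / mean(ranges),
                 tolerance = 1e-12)
    expect_equal(unname(rs$per_cycle[, k]), ranges, tolerance = 1e-12)
  }
})

test_that("range statistics on closed-form cases", {
  # identical sinusoids: every range 2A, sd = cv = 0
  p <- seq(0, 2 * pi, length.out = 101)
  cyc <- array(NA_real_, c(4, 101, 3))
  for (i in 1:4) for (k in 1:3) cyc[i, , k] <- k * 3 * sin(p)
  rs <- range_stats(cycle_set_from_array(cyc))
  expect_equal(unname(rs$mean), c(6, 12, 18), tolerance = 1e-9)
  expect_equal(unname(rs$sd), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(rs$cv), rep(0, 3), tolerance = 1e-12)
  # ranges {8, 12}: mean 10, sd 2sqrt(2), cv 28.28%
  cyc2 <- array(0, c(2, 101, 3))
  cyc2[1, , ] <- 4 * sin(p); cyc2[2, , ] <- 6 * sin(p)
  rs2 <- range_stats(cycle_set_from_array(cyc2))
  expect_equal(unname(rs2$mean), rep(10, 3), tolerance = 1e-9)
  expect_equal(unname(rs2$sd), rep(2 * sqrt(2), 3), tolerance = 1e-9)
  expect_equal(unname(rs2$cv), rep(100 * 2 * sqrt(2) / 10, 3),
               tolerance = 1e-9)
})

test_that("single-cycle sets report mean but flag sd/cv unavailable", {
  cyc <- array(stats::rnorm(101 * 3), c(1, 101, 3))
  rs <- range_stats(cycle_set_from_array(cyc))
  expect_true(all(is.finite(rs$mean)))
  expect_true(all(is.na(rs$sd)))
  expect_true(all(is.na(rs$cv)))
})

test_that("subphase_differences reads the averaged curve at 0/10/50/73/100", {
  cs <- random_cycle_set(5, seed = 33)
  sd_ <- subphase_differences(cs)
  mc <- apply(cs$cycles, c(2, 3), mean)
  marks <- c(0, 10, 50, 73, 100) + 1
  for (k in 1:3) {
    expected <- diff(mc[marks, k])
    expect_equal(unname(sd_$signed[, k]), expected, tolerance = 1e-12)
    expect_equal(unname(sd_$abs[, k]), abs(expected), tolerance = 1e-12)
  }
})

test_that("subphase differences of simple curves", {
  # linear 0..10 deg over the cycle: differences = interval widths / 10
  cyc <- array(NA_real_, c(2, 101, 3))
  for (i in 1:2) for (k in 1:3) cyc[i, , k] <- seq(0, 10, length.out = 101)
  d <- subphase_differences(cycle_set_from_array(cyc))
  expect_equal(unname(d$abs[, 1]), c(1.0, 4.0, 2.3, 2.7), tolerance = 1e-9)
  # constant curve: all zero
  cyc[] <- 5
  d0 <- subphase_differences(cycle_set_from_array(cyc))
  expect_true(all(d0$abs == 0))
})

test_that("cycle_cross_correlation equals the pairwise Pearson oracle", {
  cs <- random_cycle_set(6, seed = 34)
  xc <- cycle_cross_correlation(cs)
  for (k in 1:3) {
    vals <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      a <- cs$cycles[i, , k]; b <- cs$cycles[j, , k]
      am <- a - mean(a); bm <- b - mean(b)
      vals <- c(vals, sum(am * bm) / sqrt(sum(am^2) * sum(bm^2)))
    }
    expect_equal(unname(xc[k]), mean(vals), tolerance = 1e-12)
  }
  expect_true(all(xc >= -1 & xc <= 1))
})

test_that("cross-correlation hits the +1 / -1 endpoints", {
  p <- seq(0, 2 * pi, length.out = 101)
  same <- array(NA_real_, c(3, 101, 3))
  for (i in 1:3) for (k in 1:3) same[i, , k] <- sin(p) + k
  expect_equal(unname(cycle_cross_correlation(cycle_set_from_array(same))),
               rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  opp <- array(NA_real_, c(2, 101, 3))
  for (k in 1:3) { opp[1, , k] <- sin(p); opp[2, , k] <- -sin(p) }
  expect_equal(unname(cycle_cross_correlation(cycle_set_from_array(opp))),
               rep(-1, 3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance cycles are skipped, not propagated", {
  p <- seq(0, 2 * pi, length.out = 101)
  cyc <- array(NA_real_, c(3, 101, 3))
  cyc[1, , ] <- sin(p); cyc[2, , ] <- sin(p)
  cyc[3, , ] <- 7                              # flat cycle
  xc <- cycle_cross_correlation(cycle_set_from_array(cyc))
  expect_equal(unname(xc), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(attr(xc, "skipped_pairs")), rep(2L, 3))
  # all pairs skipped -> NA
  flat <- array(1, c(2, 101, 3))
  xcf <- cycle_cross_correlation(cycle_set_from_array(flat))
  expect_true(all(is.na(xcf)))
})

test_that("remove_offset modes behave as documented", {
  n <- 50
  ang <- relative_angle_series(rep(5, n) + sin(1:n / 9),
                               rep(-3, n) + cos(1:n / 9),
                               rep(30, n) + sin(1:n / 7),
                               100, rep(TRUE, n))
  # none: identity
  expect_equal(remove_offset(ang, "none")$rotz, ang$rotz)
  # first_sample: starts at zero
  fs <- remove_offset(ang, "first_sample")
  expect_equal(fs$rotx[1], 0)
  expect_equal(fs$roty[1], 0)
  expect_equal(fs$rotz[1], 0)
  expect_equal(unname(attr(fs, "offset")["rotz"]), ang$rotz[1])
  # idempotence
  fs2 <- remove_offset(fs, "first_sample")
  expect_equal(fs2$rotz, fs$rotz, tolerance = 1e-12)
  # static_pose subtracts the interval mean
  sp <- remove_offset(ang, "static_pose", static_interval = c(1, 10))
  expect_equal(mean(sp$rotz[1:10]), 0, tolerance = 1e-12)
  expect_error(remove_offset(ang, "static_pose"), "static_interval")
})

test_that("summary scales and stays invariant as expected", {
  cs <- random_cycle_set(5, seed = 35)
  cs2 <- cycle_set_from_array(cs$cycles * 2)
  s1 <- summarize_interaction(cs)
  s2 <- summarize_interaction(cs2)
  expect_equal(s2$overall_mean, 2 * s1$overall_mean, tolerance = 1e-12)
  expect_equal(s2$range_mean, 2 * s1$range_mean, tolerance = 1e-12)
  expect_equal(s2$range_sd, 2 * s1$range_sd, tolerance = 1e-12)
  expect_equal(s2$range_cv, s1$range_cv, tolerance = 1e-12)
  expect_equal(unclass(s2$xcorr), unclass(s1$xcorr), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("summary export writes the three tables plus JSON", {
  cs <- random_cycle_set(4, seed = 36)
  s <- summarize_interaction(cs)
  dir <- withr::local_tempdir()
  paths <- write_summary(s, dir)
  expect_true(all(file.exists(file.path(
    dir, c("summary.json", "summary_table3.csv", "summary_table4.csv",
           "summary_table5.csv")))))
  t3 <- utils::read.csv(file.path(dir, "summary_table3.csv"))
  expect_identical(t3$rotation, c("RotZ", "RotX", "RotY"))
  expect_equal(t3$overall_mean_deg[t3$rotation == "RotZ"],
               unname(s$overall_mean["rotz"]), tolerance = 1e-6)
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$n_cycles, 4)
  expect_equal(js$xcorr$rotx, unname(s$xcorr["rotx"]), tolerance = 1e-9)
})
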
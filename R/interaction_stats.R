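# Orientation-difference statistics over gait cycles: overall means,
# per-cycle rotation ranges (mean, SD, CV), sub-phase rotation differences
# on the averaged curve, and inter-cycle cross-correlation consistency.

AXES <- c("rotx", "roty", "rotz")

#' Remove the static orientation offset from an angle series
#'
#' The donning of the device leaves an initial misalignment between the
#' limb and the link; this subtracts a per-axis reference so that only
#' orientation *changes* remain. `mode = "none"` keeps the raw angles
#' (offsets are themselves informative and are retained in the headline
#' summary); `"first_sample"` subtracts the first valid sample per axis;
#' `"static_pose"` subtracts the mean over a designated still interval.
#'
#' @param angles a [relative_angle_series].
#' @param mode `"none"`, `"first_sample"` or `"static_pose"`.
#' @param static_interval integer `c(from, to)` frame range for
#'   `"static_pose"`.
#' @return a [relative_angle_series]; the subtracted values are attached as
#'   attribute `"offset"` (named per axis, zero for `"none"`).
#' @export
remove_offset <- function(angles, mode = c("none", "first_sample",
                                           "static_pose"),
                          static_interval = NULL) {
  stopifnot(inherits(angles, "relative_angle_series"))
  mode <- match.arg(mode)
  ref <- c(rotx = 0, roty = 0, rotz = 0)
  if (mode == "first_sample") {
    first <- which(angles$valid)[1]
    if (is.na(first)) stop("no valid frames", call. = FALSE)
    ref <- c(rotx = angles$rotx[first], roty = angles$roty[first],
             rotz = angles$rotz[first])
  } else if (mode == "static_pose") {
    if (is.null(static_interval) || length(static_interval) != 2L)
      stop("static_pose mode needs static_interval = c(from, to)",
           call. = FALSE)
    idx <- static_interval[1]:static_interval[2]
    idx <- idx[angles$valid[idx]]
    if (!length(idx))
      stop("static interval contains no valid frames", call. = FALSE)
    ref <- c(rotx = mean(angles$rotx[idx]), roty = mean(angles$roty[idx]),
             rotz = mean(angles$rotz[idx]))
  }
  out <- relative_angle_series(angles$rotx - ref[["rotx"]],
                               angles$roty - ref[["roty"]],
                               angles$rotz - ref[["rotz"]],
                               angles$rate, angles$valid,
                               angles$convention, angles$gimbal_lock)
  attr(out, "offset") <- ref
  out
}

#' Overall mean orientation difference
#'
#' Average of each rotation over all kept cycles and all 101 normalized
#' samples (the "O.M." column of the summary table).
#'
#' @param cycles a [gait_cycle_set].
#' @return named numeric `c(rotx=, roty=, rotz=)` in degrees.
#' @export
overall_mean <- function(cycles) {
  stopifnot(inherits(cycles, "gait_cycle_set"))
  if (dim(cycles$cycles)[1] < 1L)
    stop("no kept cycles", call. = FALSE)
  stats::setNames(apply(cycles$cycles, 3, mean), AXES)
}

#' Mean curve across cycles
#'
#' @param cycles a [gait_cycle_set].
#' @return `101 x 3` matrix (columns rotx, roty, rotz).
#' @export
mean_curve <- function(cycles) {
  stopifnot(inherits(cycles, "gait_cycle_set"))
  m <- apply(cycles$cycles, c(2, 3), mean)
  colnames(m) <- AXES
  m
}

#' Range-of-rotation statistics
#'
#' Per cycle and axis, the rotation range is max - min over the 101
#' samples. Reports the mean, sample standard deviation (n-1) and
#' coefficient of variation (100 * sd / mean, %) of those per-cycle
#' ranges, plus the range of the across-cycle mean curve for reference.
#' With a single cycle, `sd` and `cv` are `NA`.
#'
#' @param cycles a [gait_cycle_set].
#' @return list with per-axis named vectors `mean`, `sd`, `cv`,
#'   `mean_curve_range` and the `n_cycles x 3` matrix `per_cycle`.
#' @export
range_stats <- function(cycles) {
  stopifnot(inherits(cycles, "gait_cycle_set"))
  nc <- dim(cycles$cycles)[1]
  if (nc < 1L) stop("no kept cycles", call. = FALSE)
  per_cycle <- apply(cycles$cycles, c(1, 3),
                     function(v) max(v) - min(v))
  per_cycle <- matrix(per_cycle, nrow = nc, ncol = 3L,
                      dimnames = list(NULL, AXES))
  m <- colMeans(per_cycle)
  s <- if (nc >= 2L) apply(per_cycle, 2, stats::sd)
       else stats::setNames(rep(NA_real_, 3), AXES)
  cv <- ifelse(m > 0, 100 * s / m, NA_real_)
  mc <- mean_curve(cycles)
  list(mean = m, sd = s, cv = stats::setNames(cv, AXES),
       mean_curve_range = apply(mc, 2, function(v) max(v) - min(v)),
       per_cycle = per_cycle)
}

#' Sub-phase rotation differences
#'
#' Evaluates the across-cycle mean curve at the sub-phase boundaries and
#' reports, per axis and sub-phase `[a, b]`, the change
#' `mean_curve(b) - mean_curve(a)`. The summary table uses absolute
#' values; the signed change is returned alongside because decreases
#' ("negative ranges") are physically meaningful.
#'
#' @param cycles a [gait_cycle_set].
#' @return list with `abs` and `signed`, each a `4 x 3` matrix
#'   (sub-phases x axes).
#' @export
subphase_differences <- function(cycles) {
  mc <- mean_curve(cycles)
  phases <- subphase_indices()
  signed <- t(vapply(phases, function(iv)
    mc[iv[2] + 1L, ] - mc[iv[1] + 1L, ], numeric(3)))
  colnames(signed) <- AXES
  list(abs = abs(signed), signed = signed)
}

#' Inter-cycle cross-correlation consistency
#'
#' For every unordered pair of kept cycles, the zero-lag normalized
#' cross-correlation of the mean-centered 101-sample curves (the Pearson
#' correlation) is computed per axis; the score is the mean over all
#' pairs. +1 means all cycles share the same shape, -1 phase opposition,
#' 0 no relation. Pairs involving a zero-variance cycle are skipped.
#' With `max_lag > 0`, the maximum correlation over circular lags up to
#' `max_lag` samples is used instead of lag zero.
#'
#' @param cycles a [gait_cycle_set].
#' @param max_lag maximum lag in samples (default 0 = zero-lag Pearson).
#' @return named numeric `c(rotx=, roty=, rotz=)` in [-1, 1]; an axis where
#'   every pair was skipped is `NA` with attribute `"skipped_pairs"`
#'   recording the counts.
#' @export
cycle_cross_correlation <- function(cycles, max_lag = 0L) {
  stopifnot(inherits(cycles, "gait_cycle_set"))
  nc <- dim(cycles$cycles)[1]
  if (nc < 2L)
    stop("need at least 2 kept cycles for cross-correlation", call. = FALSE)
  out <- stats::setNames(rep(NA_real_, 3), AXES)
  skipped <- stats::setNames(integer(3), AXES)
  for (k in 1:3) {
    vals <- numeric()
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      a <- cycles$cycles[i, , k]
      b <- cycles$cycles[j, , k]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        skipped[k] <- skipped[k] + 1L
        next
      }
      vals <- c(vals, max_corr(a, b, max_lag))
    }
    if (length(vals)) out[k] <- mean(vals)
  }
  attr(out, "skipped_pairs") <- skipped
  out
}

max_corr <- function(a, b, max_lag) {
  if (max_lag <= 0L) return(stats::cor(a, b))
  n <- length(a)
  best <- -Inf
  for (lag in -max_lag:max_lag) {
    bs <- b[((seq_len(n) - 1 + lag) %% n) + 1]
    best <- max(best, stats::cor(a, bs))
  }
  best
}

#' Full interaction summary
#'
#' Aggregates the orientation-difference statistics for one trial (or a
#' pooled set of cycles): overall mean, range-of-rotation mean/SD/CV,
#' sub-phase differences and inter-cycle cross-correlation, per axis.
#'
#' @param cycles a [gait_cycle_set].
#' @param max_lag passed to [cycle_cross_correlation].
#' @return an object of class `interaction_summary`.
#' @export
summarize_interaction <- function(cycles, max_lag = 0L) {
  stopifnot(inherits(cycles, "gait_cycle_set"))
  nc <- dim(cycles$cycles)[1]
  if (nc < 2L)
    stop("need at least 2 kept cycles to summarize", call. = FALSE)
  rs <- range_stats(cycles)
  structure(list(
    overall_mean = overall_mean(cycles),
    range_mean = rs$mean, range_sd = rs$sd, range_cv = rs$cv,
    mean_curve_range = rs$mean_curve_range,
    subphase_diff = subphase_differences(cycles),
    xcorr = cycle_cross_correlation(cycles, max_lag),
    n_cycles = nc), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<interaction_summary> %d gait cycles\n", x$n_cycles))
  tab <- rbind(`overall mean [deg]` = x$overall_mean,
               `range mean [deg]` = x$range_mean,
               `range SD [deg]` = x$range_sd,
               `range CV [%]` = x$range_cv,
               `cross-correlation` = x$xcorr)
  colnames(tab) <- c("RotX", "RotY", "RotZ")
  print(round(tab, digits))
  cat("sub-phase |difference| [deg]:\n")
  sp <- x$subphase_diff$abs
  colnames(sp) <- c("RotX", "RotY", "RotZ")
  print(round(sp, digits))
  invisible(x)
}

#' Export an interaction summary to JSON and CSV tables
#'
#' Writes `summary.json` plus three CSV tables: the descriptive statistics
#' (per-axis overall mean, range mean/SD/CV), the sub-phase differences and
#' the cross-correlation scores.
#'
#' @param s an `interaction_summary`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"summary"`.
#' @return character vector of written paths, invisibly.
#' @export
write_summary <- function(s, dir, prefix = "summary") {
  stopifnot(inherits(s, "interaction_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  axes_out <- c("RotZ", "RotX", "RotY")
  key <- c(RotX = "rotx", RotY = "roty", RotZ = "rotz")

  json_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    n_cycles = s$n_cycles,
    overall_mean_deg = as.list(s$overall_mean),
    range_mean_deg = as.list(s$range_mean),
    range_sd_deg = as.list(s$range_sd),
    range_cv_pct = as.list(s$range_cv),
    mean_curve_range_deg = as.list(s$mean_curve_range),
    subphase_diff_abs_deg = as.data.frame(s$subphase_diff$abs),
    subphase_diff_signed_deg = as.data.frame(s$subphase_diff$signed),
    xcorr = as.list(s$xcorr)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  t3 <- data.frame(rotation = axes_out,
                   overall_mean_deg = s$overall_mean[key[axes_out]],
                   range_mean_deg = s$range_mean[key[axes_out]],
                   range_sd_deg = s$range_sd[key[axes_out]],
                   range_cv_pct = s$range_cv[key[axes_out]])
  p3 <- file.path(dir, paste0(prefix, "_table3.csv"))
  utils::write.csv(t3, p3, row.names = FALSE, quote = FALSE)

  sp <- s$subphase_diff$abs
  t4 <- data.frame(rotation = axes_out,
                   flat_foot_0_10 = sp["flat_foot", key[axes_out]],
                   heel_off_10_50 = sp["heel_off", key[axes_out]],
                   toe_off_50_73 = sp["toe_off", key[axes_out]],
                   heel_strike_73_100 = sp["heel_strike", key[axes_out]])
  p4 <- file.path(dir, paste0(prefix, "_table4.csv"))
  utils::write.csv(t4, p4, row.names = FALSE, quote = FALSE)

  t5 <- data.frame(rotation = axes_out, xcorr = s$xcorr[key[axes_out]])
  p5 <- file.path(dir, paste0(prefix, "_table5.csv"))
  utils::write.csv(t5, p5, row.names = FALSE, quote = FALSE)

  invisible(c(json_path, p3, p4, p5))
}
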
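#' Labeled marker trajectory set
#'
#' Container for labeled 3D marker trajectories from an optical
#' motion-capture system. Positions are stored in millimetres in a
#' `frames x markers x 3` array; missing samples ("gaps") are carried in an
#' explicit logical mask rather than encoded as magic values, because
#' downstream frame construction must know exactly which frames are usable.
#'
#' @param labels character vector of unique marker names.
#' @param positions numeric array `frames x markers x 3`, millimetres.
#' @param rate sampling frequency in Hz (> 0).
#' @param gap_mask logical `frames x markers` matrix, `TRUE` = missing.
#'   Defaults to all-`FALSE`. Positions under a gap are stored as `NA`.
#' @param source free-text provenance string.
#' @return An object of class `marker_trajectory_set` with fields
#'   `labels`, `positions`, `rate`, `gap_mask`, `source`.
#' @export
marker_trajectory_set <- function(labels, positions, rate,
                                  gap_mask = NULL, source = "") {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("marker labels must be unique", call. = FALSE)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("positions must be a frames x markers x 3 array", call. = FALSE)
  if (dim(positions)[2] != length(labels))
    stop("positions second dimension must match number of labels", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  n_frames <- dim(positions)[1]
  if (n_frames < 2L)
    stop("a trajectory set needs at least 2 frames", call. = FALSE)
  if (is.null(gap_mask))
    gap_mask <- matrix(FALSE, n_frames, length(labels))
  gap_mask <- matrix(as.logical(gap_mask), n_frames, length(labels))
  # gaps dominate: mask out stored coordinates so they can never leak into math
  for (j in seq_along(labels)) positions[gap_mask[, j], j, ] <- NA_real_
  if (any(!is.finite(positions[!gap_index(gap_mask)])))
    stop("non-finite position outside a gap", call. = FALSE)
  structure(
    list(labels = labels, positions = positions, rate = as.numeric(rate),
         gap_mask = gap_mask, source = source),
    class = "marker_trajectory_set")
}

# expand a frames x markers mask to frames x markers x 3 linear index
gap_index <- function(gap_mask) {
  array(rep(gap_mask, 3L), dim = c(dim(gap_mask), 3L))
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf("<marker_trajectory_set> %d markers x %d frames @ %g Hz\n",
              length(x$labels), n_frames(x), x$rate))
  cat("  markers:", paste(x$labels, collapse = ", "), "\n")
  n_gap <- sum(x$gap_mask)
  cat(sprintf("  gaps: %d samples (%.2f%%)\n", n_gap,
              100 * n_gap / length(x$gap_mask)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param t a `marker_trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(t) dim(t$positions)[1]

#' Extract one marker's trajectory
#'
#' @param t a `marker_trajectory_set`.
#' @param label marker name.
#' @return numeric `frames x 3` matrix (NA under gaps).
#' @export
marker_xyz <- function(t, label) {
  j <- match(label, t$labels)
  if (is.na(j))
    stop(sprintf("marker '%s' not present in trajectory set", label),
         call. = FALSE)
  t$positions[, j, , drop = TRUE]
}

#' Marker role map
#'
#' Maps the ten pipeline roles to concrete marker labels. Roles: thigh
#' anatomical markers `EPSD`, `EASD` (proximal), `CMD`, `CLD` (medial /
#' lateral femoral condyles); exoskeleton hip and knee motor-axis markers
#' `exoHR`, `exoKR`; the device-link cluster `R3`, `R4`, `R5`; and the
#' right-heel marker `HEEL` used for gait-event detection.
#'
#' @param ... named role = label pairs, or a single named list.
#' @return named character vector of class `marker_map`.
#' @export
#' @examples
#' marker_map(EPSD = "EPSD", EASD = "EASD", CMD = "CMD", CLD = "CLD",
#'            exoHR = "exoHR", exoKR = "exoKR", R3 = "R3", R4 = "R4",
#'            R5 = "R5", HEEL = "HEEL")
marker_map <- function(...) {
  m <- list(...)
  if (length(m) == 1L && is.list(m[[1]]) && is.null(names(m)[1]))
    m <- m[[1]]
  m <- vapply(m, as.character, character(1))
  missing <- setdiff(MARKER_ROLES, names(m))
  if (length(missing))
    stop("marker_map is missing roles: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(m), MARKER_ROLES)
  if (length(extra))
    stop("unknown marker roles: ", paste(extra, collapse = ", "),
         call. = FALSE)
  structure(m[MARKER_ROLES], class = "marker_map")
}

MARKER_ROLES <- c("EPSD", "EASD", "CMD", "CLD",
                  "exoHR", "exoKR", "R3", "R4", "R5", "HEEL")

#' Default marker map (roles named after themselves)
#' @return a `marker_map`.
#' @export
default_marker_map <- function() {
  marker_map(stats::setNames(as.list(MARKER_ROLES), MARKER_ROLES))
}

#' Read a marker map from a YAML or JSON config
#'
#' Expects a top-level `markers:` mapping of role to label.
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a `marker_map`.
#' @export
read_marker_map <- function(path) {
  cfg <- read_config(path)
  if (is.null(cfg$markers))
    stop("config has no 'markers' section: ", path, call. = FALSE)
  marker_map(cfg$markers)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

check_markers_present <- function(t, m, roles) {
  labels <- unlist(m[roles], use.names = FALSE)
  absent <- setdiff(labels, t$labels)
  if (length(absent))
    stop("required markers absent from trajectory set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read marker trajectories from the plain-text CSV dialect
#'
#' The dialect is: one metadata line `# rate=<Hz> units=<mm|m>`, a header
#' row `frame,<label>_x,<label>_y,<label>_z,...` and one row per frame with
#' a 0-based frame index. Empty cells encode gaps; if any coordinate of a
#' marker is empty in a frame, the whole sample is treated as a gap.
#'
#' @param path CSV file path.
#' @return a [marker_trajectory_set] in millimetres.
#' @export
read_csv_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("not a trajectory CSV (need metadata, header and >= 2 frames): ",
         path, call. = FALSE)
  meta <- lines[1]
  if (!grepl("^#", meta))
    stop("missing '# rate=... units=...' metadata line: ", path, call. = FALSE)
  rate <- as.numeric(sub(".*rate=([0-9.eE+-]+).*", "\\1", meta))
  units <- sub(".*units=([A-Za-z]+).*", "\\1", meta)
  if (!is.finite(rate))
    stop("metadata line does not declare a numeric rate: ", path, call. = FALSE)
  if (!units %in% c("mm", "m"))
    stop("units must be 'mm' or 'm', got '", units, "': ", path, call. = FALSE)

  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(header) < 4L || header[1] != "frame")
    stop("missing header row starting with 'frame': ", path, call. = FALSE)
  coord_cols <- header[-1]
  if (length(coord_cols) %% 3L != 0L)
    stop("header must hold _x,_y,_z triplets per marker: ", path, call. = FALSE)
  labels <- unique(sub("_[xyz]$", "", coord_cols))
  expect <- as.vector(t(outer(labels, c("_x", "_y", "_z"), paste0)))
  if (!identical(coord_cols, expect))
    stop("header columns must be <label>_x,<label>_y,<label>_z per marker: ",
         path, call. = FALSE)

  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  # a trailing sentinel delimiter keeps empty trailing cells in the split
  cells <- strsplit(paste0(body, ","), ",", fixed = TRUE)
  ncol_exp <- length(header)
  n <- length(body)
  pos <- array(NA_real_, dim = c(n, length(labels), 3L))
  for (i in seq_len(n)) {
    row <- cells[[i]]
    if (length(row) != ncol_exp)
      stop(sprintf("row %d has %d columns, header has %d: %s",
                   i, length(row), ncol_exp, path), call. = FALSE)
    vals <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(vals) & nzchar(trimws(row[-1])))
    if (length(bad))
      stop(sprintf("non-numeric cell in data row %d (column '%s'): %s",
                   i, coord_cols[bad[1]], path), call. = FALSE)
    pos[i, , ] <- matrix(vals, ncol = 3L, byrow = TRUE)
  }
  gap <- apply(is.na(pos), c(1, 2), any)
  pos[gap_index(gap)] <- NA_real_
  if (units == "m") pos <- pos * 1000
  marker_trajectory_set(labels, pos, rate, gap,
                        source = paste0("csv:", path))
}

#' Fill short interior gaps by cubic-spline interpolation
#'
#' Replaces interior gaps of length `<= max_gap` frames with a cubic spline
#' fitted through the marker's valid samples, clearing the gap mask there.
#' Longer gaps and leading/trailing gaps are left untouched: extrapolating
#' a marker trajectory invents data, so edges stay missing and downstream
#' frames stay invalid there.
#'
#' @param t a [marker_trajectory_set].
#' @param max_gap longest gap run (frames) that will be filled;
#'   default 10 frames (0.1 s at 100 Hz).
#' @return a new [marker_trajectory_set] with gaps filled.
#' @export
fill_gaps <- function(t, max_gap = 10L) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  pos <- t$positions
  gap <- t$gap_mask
  n <- n_frames(t)
  for (j in seq_along(t$labels)) {
    gj <- gap[, j]
    if (!any(gj)) next
    if (all(gj))
      stop(sprintf("marker '%s' has no valid samples at all", t$labels[j]),
           call. = FALSE)
    if (max_gap == 0) next
    valid <- which(!gj)
    runs <- rle(gj)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      s <- starts[r]; e <- ends[r]
      if (s == 1L || e == n) next            # leading/trailing: do not fill
      if (runs$lengths[r] > max_gap) next
      idx <- s:e
      for (k in 1:3) {
        f <- stats::splinefun(valid, pos[valid, j, k], method = "fmm")
        pos[idx, j, k] <- f(idx)
      }
      gap[idx, j] <- FALSE
    }
  }
  marker_trajectory_set(t$labels, pos, t$rate, gap,
                        source = paste0(t$source, " +fill_gaps"))
}

#' Low-pass filter marker trajectories
#'
#' Zero-phase Butterworth filtering of every marker coordinate, the
#' standard conditioning step before differentiating or building segment
#' frames: voluntary gait content lives below a few Hz while optical
#' marker noise is broadband, so a 6 Hz cutoff removes most noise without
#' touching the signal. Each contiguous gap-free run is filtered
#' independently; runs shorter than three filter lengths are left as-is,
#' and gaps are never bridged.
#'
#' @param t a [marker_trajectory_set].
#' @param cutoff_hz low-pass cutoff in Hz, default 6.
#' @param order Butterworth order, default 4.
#' @return a smoothed [marker_trajectory_set].
#' @export
smooth_trajectories <- function(t, cutoff_hz = 6, order = 4L) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  if (cutoff_hz <= 0 || cutoff_hz >= t$rate / 2)
    stop("cutoff_hz must lie in (0, rate/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (t$rate / 2), type = "low")
  min_run <- 3L * (order + 1L)
  pos <- t$positions
  for (j in seq_along(t$labels)) {
    runs <- rle(!t$gap_mask[, j])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= min_run)) {
      idx <- starts[r]:ends[r]
      for (k in 1:3)
        pos[idx, j, k] <- filtfilt_padded(bf, pos[idx, j, k])
    }
  }
  marker_trajectory_set(t$labels, pos, t$rate, t$gap_mask,
                        source = paste0(t$source, sprintf(
                          " +lowpass%gHz", cutoff_hz)))
}

#' Write marker trajectories to the plain-text CSV dialect
#'
#' Inverse of [read_csv_trajectories]; finite values survive the round trip
#' exactly (17 significant digits). Gap samples are written as empty cells.
#'
#' @param t a [marker_trajectory_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_trajectories <- function(t, path) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  n <- n_frames(t)
  header <- c("frame",
              as.vector(t(outer(t$labels, c("_x", "_y", "_z"), paste0))))
  rows <- character(n)
  for (i in seq_len(n)) {
    vals <- as.vector(t(t$positions[i, , , drop = FALSE][1, , ]))
    cells <- ifelse(is.na(vals), "", sprintf("%.17g", vals))
    rows[i] <- paste(c(as.character(i - 1L), cells), collapse = ",")
  }
  writeLines(c(sprintf("# rate=%.17g units=mm", t$rate),
               paste(header, collapse = ","), rows), path)
  invisible(path)
}
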
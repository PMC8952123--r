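# Minimal C3D (coordinate 3D) reader/writer.
#
# Implements the Intel (processor type 84) subset of the public c3d.org
# format: a 512-byte header block, a parameter section describing the POINT
# group, and frame-sequential point data. Floating-point point storage is
# written; both float and scaled-integer storage are read. Analog channels
# are ignored. This is deliberately a small, well-tested subset — enough to
# interchange labeled marker trajectories with standard motion-capture
# software — not a general C3D toolkit.

C3D_BLOCK <- 512L

#' Read labeled point trajectories from a C3D file
#'
#' Reads all labeled 3D points from a C3D motion-capture file. Coordinates
#' are returned in millimetres (files declaring `POINT:UNITS` of metres are
#' converted). A sample is masked as a gap when its residual word flags it
#' invalid (negative residual) or when the stored coordinates are exactly
#' (0, 0, 0), the convention motion-capture pipelines use for unlabeled
#' spans.
#'
#' @param path C3D file path.
#' @return a [marker_trajectory_set].
#' @export
read_c3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2L * C3D_BLOCK)
    stop("not a valid C3D file (truncated): ", path, call. = FALSE)
  if (as.integer(raw[2]) != 0x50L)
    stop("not a valid C3D file (bad magic byte): ", path, call. = FALSE)

  rcon <- rawConnection(raw)
  on.exit(close(rcon))
  hdr_param_block <- readBin(rcon, "integer", 1, size = 1, signed = FALSE)
  readBin(rcon, "raw", 1)                       # magic, already checked
  n_points <- readBin(rcon, "integer", 1, size = 2, endian = "little")
  readBin(rcon, "integer", 1, size = 2, endian = "little")  # analog/frame
  first_frame <- readBin(rcon, "integer", 1, size = 2, endian = "little")
  last_frame <- readBin(rcon, "integer", 1, size = 2, signed = FALSE,
                        endian = "little")
  readBin(rcon, "integer", 1, size = 2, endian = "little")  # max gap
  hdr_scale <- readBin(rcon, "numeric", 1, size = 4, endian = "little")
  hdr_data_start <- readBin(rcon, "integer", 1, size = 2, endian = "little")
  readBin(rcon, "integer", 1, size = 2, endian = "little")  # analog per frame
  hdr_rate <- readBin(rcon, "numeric", 1, size = 4, endian = "little")

  p <- parse_c3d_parameters(raw, hdr_param_block, path)
  point <- p$groups[["POINT"]]
  if (is.null(point))
    stop("C3D file has no POINT parameter group: ", path, call. = FALSE)

  n_used <- c3d_param(point, "USED", n_points)
  n_frames <- c3d_param(point, "FRAMES", last_frame - first_frame + 1L)
  scale <- c3d_param(point, "SCALE", hdr_scale)
  rate <- c3d_param(point, "RATE", hdr_rate)
  data_start <- c3d_param(point, "DATA_START", hdr_data_start)
  labels <- point$params[["LABELS"]]$value
  if (is.null(labels)) labels <- sprintf("M%03d", seq_len(n_used))
  labels <- trimws(labels)[seq_len(n_used)]

  units <- point$params[["UNITS"]]$value
  src <- paste0("c3d:", path)
  if (is.null(units)) {
    warning("C3D file declares no POINT:UNITS; assuming millimetres: ", path)
    units <- "mm"
    src <- paste0(src, " (units assumed mm)")
  }
  units <- trimws(units[1])
  unit_factor <- if (identical(units, "m")) 1000 else 1

  if (n_used < 1L || n_frames < 2L)
    stop("C3D file holds no usable point data: ", path, call. = FALSE)

  is_float <- scale < 0
  word <- if (is_float) 4L else 2L
  need <- (data_start - 1L) * C3D_BLOCK + n_frames * n_used * 4L * word
  if (length(raw) < need)
    stop("C3D point data section is truncated: ", path, call. = FALSE)

  dcon <- rawConnection(raw[((data_start - 1L) * C3D_BLOCK + 1L):length(raw)])
  on.exit(close(dcon), add = TRUE)
  nvals <- n_frames * n_used * 4L
  if (is_float) {
    vals <- readBin(dcon, "numeric", nvals, size = 4, endian = "little")
  } else {
    vals <- readBin(dcon, "integer", nvals, size = 2, endian = "little")
  }
  m <- matrix(vals, nrow = 4L)           # x, y, z, residual per point sample
  xyz <- m[1:3, , drop = FALSE]
  if (!is_float) xyz <- xyz * scale
  resid <- m[4, ]

  pos <- array(NA_real_, dim = c(n_frames, n_used, 3L))
  # samples are ordered point-fastest within each frame
  for (k in 1:3)
    pos[, , k] <- matrix(xyz[k, ], nrow = n_frames, ncol = n_used,
                         byrow = TRUE)
  gap <- matrix(resid < 0, nrow = n_frames, ncol = n_used, byrow = TRUE)
  zero <- pos[, , 1] == 0 & pos[, , 2] == 0 & pos[, , 3] == 0
  gap <- gap | zero
  pos <- pos * unit_factor
  marker_trajectory_set(labels, pos, rate, gap, source = src)
}

# Parse the parameter section into groups[name] = list(params = list(...)).
parse_c3d_parameters <- function(raw, param_block, path) {
  off <- (param_block - 1L) * C3D_BLOCK
  proc <- as.integer(raw[off + 4L])
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc,
         " (only Intel/PC files are supported): ", path, call. = FALSE)
  i <- off + 5L                                   # first group/param record
  group_names <- character()                      # id -> name
  records <- list()                               # list of (gid, name, value)
  repeat {
    if (i + 1L > length(raw)) break
    name_len <- readBin(raw[i], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw[i + 1L], "integer", size = 1, signed = TRUE)
    n <- abs(name_len)
    if (n == 0L || gid == 0L) break
    name <- rawToChar(raw[(i + 2L):(i + 1L + n)])
    po <- i + 2L + n
    nxt <- readBin(raw[po:(po + 1L)], "integer", size = 2, endian = "little")
    if (gid < 0L) {                               # group record
      group_names[as.character(-gid)] <- name
    } else {                                      # parameter record
      etype <- readBin(raw[po + 2L], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[po + 3L])
      dims <- if (ndim > 0)
        as.integer(raw[(po + 4L):(po + 3L + ndim)]) else integer()
      nel <- prod(c(1L, dims))
      esize <- abs(etype)
      dstart <- po + 4L + ndim
      bytes <- raw[dstart:(dstart + nel * esize - 1L)]
      value <- switch(as.character(etype),
        "-1" = {                                  # character data
          if (ndim <= 1L) trimws(rawToChar(bytes))
          else {
            w <- dims[1]
            n_str <- nel %/% w
            vapply(seq_len(n_str), function(s)
              trimws(rawToChar(bytes[((s - 1L) * w + 1L):(s * w)])),
              character(1))
          }
        },
        "1" = as.integer(bytes),
        "2" = readBin(bytes, "integer", nel, size = 2, endian = "little"),
        "4" = readBin(bytes, "numeric", nel, size = 4, endian = "little"),
        stop("bad C3D parameter element type: ", path, call. = FALSE))
      records[[length(records) + 1L]] <- list(gid = gid, name = name,
                                              value = value)
    }
    if (nxt == 0L) break
    i <- po + 2L + nxt                            # offset counts from the
                                                  # byte after the offset word
  }
  groups <- list()
  for (rec in records) {
    gname <- group_names[as.character(rec$gid)]
    if (is.na(gname)) next
    groups[[gname]]$params[[rec$name]] <- list(value = rec$value)
  }
  list(groups = groups)
}

c3d_param <- function(group, name, fallback) {
  v <- group$params[[name]]$value
  if (is.null(v) || !length(v)) fallback else as.numeric(v[1])
}

#' Write a trajectory set to a C3D file
#'
#' Emits an Intel floating-point C3D file with a POINT parameter group
#' (USED, FRAMES, RATE, SCALE, DATA_START, UNITS in mm, LABELS). Gap
#' samples are stored as (0, 0, 0) with a negative residual, the zero-span
#' convention used by capture pipelines.
#'
#' @param t a [marker_trajectory_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(t, path) {
  stopifnot(inherits(t, "marker_trajectory_set"))
  nf <- n_frames(t)
  np <- length(t$labels)
  if (nf > 65535L)
    stop("C3D writer supports at most 65535 frames", call. = FALSE)

  lab_w <- max(4L, max(nchar(t$labels)))
  labels_padded <- formatC(t$labels, width = lab_w, flag = "-")

  param_raw <- c(
    as.raw(c(0x01, 0x50, 0x00, 0x54)),       # filled in: block count byte 3
    c3d_group_record("POINT", 1L),
    c3d_param_record("USED", 1L, 2L, np),
    c3d_param_record("FRAMES", 1L, 2L, nf),
    c3d_param_record("RATE", 1L, 4L, t$rate),
    c3d_param_record("SCALE", 1L, 4L, -1),
    c3d_param_record("UNITS", 1L, -1L, "mm"),
    c3d_param_record("LABELS", 1L, -1L, labels_padded, char_width = lab_w),
    c3d_param_record("DATA_START", 1L, 2L, 0L, last = TRUE)  # patched below
  )
  n_param_blocks <- as.integer(ceiling(length(param_raw) / C3D_BLOCK))
  data_start <- 2L + n_param_blocks
  param_raw[3] <- as.raw(n_param_blocks)
  # patch DATA_START value: last record, value is the final 2 data bytes
  # before its trailing desc-length byte
  ds_at <- length(param_raw) - 2L
  param_raw[ds_at:(ds_at + 1L)] <- writeBin(data_start, raw(), size = 2,
                                            endian = "little")
  param_raw <- c(param_raw,
                 raw(n_param_blocks * C3D_BLOCK - length(param_raw)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(2L, 0x50L)), con)
  writeBin(as.integer(c(np, 0L, 1L, nf, 0L)), con, size = 2,
           endian = "little")
  writeBin(-1, con, size = 4, endian = "little")          # header scale
  writeBin(as.integer(c(data_start, 0L)), con, size = 2, endian = "little")
  writeBin(t$rate, con, size = 4, endian = "little")
  writeBin(raw(C3D_BLOCK - 24L), con)                     # header padding
  writeBin(param_raw, con)

  pos <- t$positions
  pos[is.na(pos)] <- 0
  resid <- ifelse(t$gap_mask, -1, 0)
  out <- numeric(nf * np * 4L)
  dim(out) <- c(4L, np, nf)
  for (k in 1:3) out[k, , ] <- t(pos[, , k])
  out[4, , ] <- t(resid)
  writeBin(as.numeric(out), con, size = 4, endian = "little")
  invisible(path)
}

c3d_group_record <- function(name, id) {
  nb <- charToRaw(name)
  desc <- raw(0)
  nxt <- 1L + length(desc)                       # desc-length byte + desc
  c(as.raw(length(nb)), writeBin(-id, raw(), size = 1),
    nb, writeBin(as.integer(nxt), raw(), size = 2, endian = "little"),
    as.raw(length(desc)), desc)
}

c3d_param_record <- function(name, gid, etype, value, char_width = NULL,
                             last = FALSE) {
  nb <- charToRaw(name)
  if (etype == -1L) {
    strs <- as.character(value)
    if (is.null(char_width)) char_width <- nchar(strs[1])
    data <- charToRaw(paste(strs, collapse = ""))
    dims <- if (length(strs) > 1L) c(char_width, length(strs))
            else char_width
  } else if (etype == 2L) {
    data <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    dims <- if (length(value) > 1L) length(value) else integer()
  } else {
    data <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
    dims <- if (length(value) > 1L) length(value) else integer()
  }
  body <- c(writeBin(as.integer(etype), raw(), size = 1),
            as.raw(length(dims)), as.raw(dims), data, as.raw(0L))
  nxt <- if (last) 0L else length(body)
  c(as.raw(length(nb)), as.raw(gid), nb,
    writeBin(as.integer(nxt), raw(), size = 2, endian = "little"), body)
}
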
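#' Tomogram volume container
#'
#' A `tomogram_volume` is a 3D scalar field with a voxel size in Angstrom.
#' The in-memory convention is fixed: 0-based voxel indices, the first array
#' axis is x (fastest-varying, matching the MRC column axis), the second is y,
#' and the third (z) is the beam/thickness axis. Crops are half-open.
#'
#' @param voxels numeric 3D array of shape (W, H, D); all values finite.
#' @param voxel_size voxel edge length in Angstrom (isotropic).
#' @return an object of class `tomogram_volume` with elements `voxels`,
#'   `voxel_size` and `origin_convention`.
#' @export
tomogram_volume <- function(voxels, voxel_size = 1) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L))
    stop("all volume dimensions must be >= 1")
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         origin_convention = "0-based, x fastest, z is beam/thickness axis"),
    class = "tomogram_volume")
}

#' @export
print.tomogram_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tomogram_volume %d x %d x %d, %.3g A/voxel>\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

as_volume_array <- function(vol) {
  if (inherits(vol, "tomogram_volume")) vol$voxels else {
    stopifnot(length(dim(vol)) == 3L)
    vol
  }
}

mrc_machst_le <- as.raw(c(0x44, 0x44, 0x00, 0x00))

write_mrc_data <- function(data, voxel_size, path, is_stack = FALSE) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * voxel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(if (is_stack) 0L else 1L)  # ispg
  wi(0L)                     # nsymbt
  writeBin(raw(100), con)    # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(mrc_machst_le, con)
  wf(sd(as.numeric(data)))
  wi(0L)                     # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(NULL)
}

read_mrc_data <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (length(d) < 3 || any(is.na(d)) || any(d < 1L) || any(d > 1e5))
    stop("corrupt MRC header: bad dimensions")
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode: ", mode)
  ri(3)                    # nxstart
  m <- ri(3)               # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3)      # cellb, map axes, dmin/dmax/dmean
  ri(1)                    # ispg
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(data) != n) stop("corrupt MRC file: truncated data section")
  voxel_size <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  list(data = array(data, dim = d), voxel_size = voxel_size)
}

#' Read a tomogram volume from an MRC file
#'
#' Supports MRC2014 modes 0, 1 and 2 (data is always promoted to double).
#' The MRC column/row/section axes map onto the in-memory (x, y, z) order.
#'
#' @param path path to an MRC file.
#' @return a [tomogram_volume()].
#' @export
read_volume <- function(path) {
  m <- read_mrc_data(path)
  tomogram_volume(m$data, m$voxel_size)
}

#' Write a tomogram volume to an MRC file (mode 2, float32)
#'
#' @param vol a [tomogram_volume()] or bare 3D array.
#' @param path output path.
#' @param voxel_size voxel size in Angstrom; taken from `vol` when it is a
#'   `tomogram_volume`.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  vs <- if (inherits(vol, "tomogram_volume")) vol$voxel_size
        else if (is.null(voxel_size)) 1 else voxel_size
  write_mrc_data(as_volume_array(vol), vs, path, is_stack = FALSE)
  invisible(path)
}

#' Tilt-series container
#'
#' A list of 2D projection images with one tilt angle per image. The tilt axis
#' is y; angles are in degrees, strictly increasing, with magnitude below 90.
#'
#' @param images list of 2D numeric matrices, all the same shape (W, H).
#' @param angles numeric vector of tilt angles in degrees.
#' @return an object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles) {
  if (length(images) != length(angles))
    stop("need exactly one tilt angle per image")
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("tilt angles must be strictly increasing")
  if (any(abs(angles) >= 90))
    stop("tilt angles must satisfy |theta| < 90")
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) stop("all tilt images must share one shape")
  structure(list(images = images, angles = as.numeric(angles)),
            class = "tilt_series")
}

#' Write a tilt series as an MRC stack plus a plain-text angle file
#'
#' @param tilts a [tilt_series()].
#' @param path output MRC path; angles go to `paste0(path, ".tlt")` unless
#'   `angles_path` is given.
#' @param angles_path optional path for the angle list.
#' @param voxel_size pixel size in Angstrom.
#' @export
write_tilt_series <- function(tilts, path, angles_path = NULL, voxel_size = 1) {
  stopifnot(inherits(tilts, "tilt_series"))
  d2 <- dim(tilts$images[[1]])
  stack <- array(unlist(tilts$images), dim = c(d2, length(tilts$images)))
  write_mrc_data(stack, voxel_size, path, is_stack = TRUE)
  if (is.null(angles_path)) angles_path <- paste0(path, ".tlt")
  writeLines(formatC(tilts$angles, format = "f", digits = 2), angles_path)
  invisible(path)
}

#' Read a tilt series from an MRC stack and an angle file
#'
#' @param path MRC stack path.
#' @param angles_path angle list path; defaults to `paste0(path, ".tlt")`.
#' @return a [tilt_series()].
#' @export
read_tilt_series <- function(path, angles_path = NULL) {
  if (is.null(angles_path)) angles_path <- paste0(path, ".tlt")
  m <- read_mrc_data(path)
  angles <- as.numeric(readLines(angles_path))
  d <- dim(m$data)
  images <- lapply(seq_len(d[3]), function(i) m$data[, , i])
  tilt_series(images, angles)
}
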
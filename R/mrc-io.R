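# Minimal MRC2014 I/O. Volumes and stacks are written as mode 2 (32-bit
# float, little endian) with the pixel size recorded in the cell dimensions;
# modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are read.

#' Read an MRC2014 file
#'
#' @param path Path to the MRC file.
#' @param as One of `"volume"` (return a [tomo_volume()], axes x, y, z),
#'   `"stack"` (return the raw `(nx, ny, nz)` array with `pixel_size`
#'   attribute; combine with a .tlt file via [tilt_series()]) or `"auto"`
#'   (volume when `ispg >= 1`, stack otherwise).
#' @return A `tomo_volume` or a plain array with a `pixel_size` attribute.
#' @export
read_mrc <- function(path, as = c("auto", "volume", "stack")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_int[1L]; ny <- hdr_int[2L]; nz <- hdr_int[3L]; mode <- hdr_int[4L]
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, 22L * 4L)  # word 23: ispg
  ispg <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 1024L + nsymbt)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d", mode), call. = FALSE))
  if (length(data) != n) stop("truncated MRC payload", call. = FALSE)
  dim(data) <- c(nx, ny, nz)
  px <- if (mxyz[1L] > 0 && cella[1L] > 0) cella[1L] / mxyz[1L] else 1
  if (as == "volume" || (as == "auto" && ispg >= 1L))
    tomo_volume(data, px)
  else
    structure(data, pixel_size = px)
}

#' Write an MRC2014 file (mode 2, 32-bit float)
#'
#' @param x A [tomo_volume()], [tilt_series()] or 3D array (a matrix is
#'   promoted to one section).
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom (defaults to the object's).
#' @param is_volume Write as a volume (`ispg = 1`) rather than an image
#'   stack (`ispg = 0`); defaults by class.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size = NULL, is_volume = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(x, "pixel_size")
  if (is.null(pixel_size)) stop("`pixel_size` is required", call. = FALSE)
  if (is.null(is_volume)) is_volume <- inherits(x, "tomo_volume")
  data <- unclass(x)
  attributes(data) <- list(dim = dim(data))
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  # round through float32 up front so the header statistics describe the
  # stored payload exactly (write -> read -> write is then byte-stable)
  data <- readBin(writeBin(as.vector(data), raw(), size = 4L,
                           endian = "little"),
                  "numeric", n = length(data), size = 4L, endian = "little")
  dim(data) <- d
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(c(d, 2L))                  # nx ny nz mode
  wi(c(0L, 0L, 0L))             # nxstart nystart nzstart
  wi(d)                         # mx my mz
  wf(d * pixel_size)            # cella
  wf(c(90, 90, 90))             # cellb
  wi(c(1L, 2L, 3L))             # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))  # dmin dmax dmean
  wi(if (is_volume) 1L else 0L) # ispg
  wi(0L)                        # nsymbt
  wi(rep(0L, 25L))              # extra (words 26..50)
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little endian
  wf(stats::sd(data))           # rms
  wi(0L)                        # nlabl
  writeBin(raw(800L), con)      # labels
  wf(data)
  invisible(path)
}
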
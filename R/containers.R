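#' Tomographic volume container
#'
#' A 3D real array `(nx, ny, nz)` with a pixel size and optional provenance
#' metadata (correction mode, defocus step). The y axis is the tilt axis;
#' x runs across it and z along the beam at zero tilt.
#'
#' @param data 3D numeric array (a 2D matrix is promoted to `ny = 1`).
#' @param pixel_size Pixel size in Angstrom.
#' @param metadata Optional named list of provenance fields.
#' @return An object of class `tomo_volume` (a plain array with attributes).
#' @export
tomo_volume <- function(data, pixel_size, metadata = list()) {
  if (is.matrix(data)) {
    d <- dim(data)
    dim(data) <- c(d[1L], 1L, d[2L])
  }
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  structure(data, pixel_size = pixel_size, metadata = metadata,
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("tomo_volume: %d x %d x %d voxels, %.3g A/px\n",
              d[1L], d[2L], d[3L], attr(x, "pixel_size")))
  md <- attr(x, "metadata")
  if (length(md)) cat("  ", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

unclass_volume <- function(x) {
  y <- unclass(x)
  attr(y, "pixel_size") <- NULL
  attr(y, "metadata") <- NULL
  y
}

restore_volume <- function(data, template) {
  if (inherits(template, "tomo_volume"))
    tomo_volume(data, attr(template, "pixel_size"), attr(template, "metadata"))
  else data
}

#' Tilt-series container
#'
#' A stack of 2D projection images `(nx, ny, n_tilts)` with one tilt angle
#' per image. Rows (x) run across the tilt axis; columns (y) are shared with
#' the reconstruction volume's y axis.
#'
#' @param data 3D numeric array `(nx, ny, n_tilts)`.
#' @param tilt_angles Tilt angles in degrees, one per image, strictly inside
#'   (-90, 90).
#' @param pixel_size Pixel size in Angstrom.
#' @return An object of class `tilt_series`.
#' @export
tilt_series <- function(data, tilt_angles, pixel_size) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array (nx, ny, n_tilts)", call. = FALSE)
  if (dim(data)[3L] != length(tilt_angles))
    stop("one tilt angle per image is required", call. = FALSE)
  if (any(abs(tilt_angles) >= 90))
    stop("tilt angles must lie strictly inside (-90, 90) degrees", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  structure(data, tilt_angles = as.numeric(tilt_angles),
            pixel_size = pixel_size, class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x)
  a <- attr(x, "tilt_angles")
  cat(sprintf("tilt_series: %d images of %d x %d px, %.3g A/px, tilts %g..%g deg\n",
              d[3L], d[1L], d[2L], attr(x, "pixel_size"), min(a), max(a)))
  invisible(x)
}
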
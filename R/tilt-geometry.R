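#' Acquisition/reconstruction geometry of a tilt series
#'
#' Fixes the convention used throughout the package: the tilt axis is the
#' y axis ("zero x-tilt"), voxel coordinates are centred (0 at the volume
#' centre, which sits at index `floor(n/2)` per axis), and defocus is stored
#' in nm with underfocus positive. The height of a point along the beam at
#' tilt angle `a` is `h = -x sin(a) + z cos(a)` (voxels); points higher along
#' the beam are closer to the lens and therefore less underfocused.
#'
#' @param dim Volume dimensions `c(nx, ny, nz)` in voxels.
#' @param pixel_size Pixel size in Angstrom.
#' @param tilt_angles Tilt angles in degrees, strictly inside (-90, 90).
#' @param center_defocus Per-tilt nominal defocus (nm) at the volume centre;
#'   a scalar is recycled to all tilts.
#' @param z_shift Defocus offset (nm) added to all centre defoci when the
#'   volume centre is not at the nominal defocus (default 0).
#' @param invert_handedness Flip the sign of x in the height formula for
#'   data with the opposite tilt-axis polarity.
#' @return An object of class `tilt_geometry`.
#' @export
tilt_geometry <- function(dim, pixel_size, tilt_angles, center_defocus,
                          z_shift = 0, invert_handedness = FALSE) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("`dim` must be three positive integers c(nx, ny, nz)", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (any(abs(tilt_angles) >= 90))
    stop("tilt angles must lie strictly inside (-90, 90) degrees", call. = FALSE)
  if (length(center_defocus) == 1L)
    center_defocus <- rep(center_defocus, length(tilt_angles))
  if (length(center_defocus) != length(tilt_angles))
    stop("`center_defocus` must have one value per tilt", call. = FALSE)
  structure(
    list(dim = dim, pixel_size = pixel_size,
         tilt_angles = as.numeric(tilt_angles),
         center_defocus = as.numeric(center_defocus),
         z_shift = z_shift, invert_handedness = isTRUE(invert_handedness)),
    class = "tilt_geometry")
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("tilt_geometry: %d x %d x %d voxels, %.3g A/px, %d tilts (%g..%g deg)\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$pixel_size,
              length(x$tilt_angles), min(x$tilt_angles), max(x$tilt_angles)))
  cat(sprintf("  centre defocus %g..%g nm, z-shift %g nm\n",
              min(x$center_defocus), max(x$center_defocus), x$z_shift))
  invisible(x)
}

# Centred voxel coordinates along one axis: index i (1-based) -> i-1-floor(n/2)
centered_coords <- function(n) seq_len(n) - 1 - floor(n / 2)

#' Defocus of a point in the volume at one tilt
#'
#' @param geom A [tilt_geometry()] object.
#' @param x,z Centred coordinates of the point in voxels from the volume
#'   centre (may be fractional; vectorised).
#' @param tilt_index Index into `geom$tilt_angles`.
#' @return Defocus in nm:
#'   `center_defocus[i] + z_shift - h * pixel_size * 0.1` with
#'   `h = -x sin(a) + z cos(a)`.
#' @export
point_defocus <- function(geom, x, z, tilt_index) {
  stopifnot(inherits(geom, "tilt_geometry"))
  if (tilt_index < 1L || tilt_index > length(geom$tilt_angles))
    stop("`tilt_index` out of range", call. = FALSE)
  a <- geom$tilt_angles[tilt_index] * pi / 180
  xs <- if (geom$invert_handedness) -x else x
  h <- -xs * sin(a) + z * cos(a)
  geom$center_defocus[tilt_index] + geom$z_shift - h * geom$pixel_size * 0.1
}

#' Plan the per-tilt correction defoci
#'
#' For each tilt the defocus span across the volume is
#' `range = (nx |sin a| + nz |cos a|) * pixel_size * 0.1` nm; the plan places
#' `n = floor(range / step) + 1` defoci spaced exactly `step` nm, centred on
#' (and symmetric about) that tilt's centre defocus. A step at least as large
#' as every span degenerates to single-defocus (2D-style) correction.
#'
#' @param geom A [tilt_geometry()] object.
#' @param defocus_step Defocus step in nm (> 0).
#' @return An object of class `defocus_plan`: per-tilt defocus vectors plus
#'   the step.
#' @export
plan_defocus_planes <- function(geom, defocus_step) {
  stopifnot(inherits(geom, "tilt_geometry"))
  if (!is.numeric(defocus_step) || defocus_step <= 0)
    stop("`defocus_step` must be > 0 (nm)", call. = FALSE)
  a <- geom$tilt_angles * pi / 180
  span <- (geom$dim[1L] * abs(sin(a)) + geom$dim[3L] * abs(cos(a))) *
    geom$pixel_size * 0.1
  n <- pmax(1L, floor(span / defocus_step) + 1L)
  defoci <- lapply(seq_along(a), function(i) {
    geom$center_defocus[i] + geom$z_shift +
      (seq_len(n[i]) - (n[i] + 1) / 2) * defocus_step
  })
  structure(list(defoci = defoci, n = as.integer(n), step = defocus_step),
            class = "defocus_plan")
}

#' @export
print.defocus_plan <- function(x, ...) {
  cat(sprintf("defocus_plan: step %g nm, planes per tilt %d..%d (total %d corrections)\n",
              x$step, min(x$n), max(x$n), sum(x$n)))
  invisible(x)
}

#' Precompute the defocus-index array
#'
#' For every voxel column position `(x, z)` and every tilt, stores the index
#' of the planned correction defocus nearest to [point_defocus()] at that
#' position (ties broken toward the lower index). Because the tilt axis is y,
#' the array never depends on y: one xz-plane per tilt suffices.
#'
#' @param geom A [tilt_geometry()] object.
#' @param plan A [defocus_plan()] from [plan_defocus_planes()] for the same
#'   geometry.
#' @return Integer array `(nx, nz, n_tilts)`; entry values lie in
#'   `1..plan$n[i]` for tilt i.
#' @export
build_defocus_array <- function(geom, plan) {
  stopifnot(inherits(geom, "tilt_geometry"), inherits(plan, "defocus_plan"))
  if (length(plan$defoci) != length(geom$tilt_angles))
    stop("plan and geometry have different tilt counts", call. = FALSE)
  nx <- geom$dim[1L]; nz <- geom$dim[3L]
  xc <- centered_coords(nx); zc <- centered_coords(nz)
  out <- array(0L, c(nx, nz, length(geom$tilt_angles)))
  for (i in seq_along(geom$tilt_angles)) {
    d <- outer(xc, zc, function(x, z) point_defocus(geom, x, z, i))
    q <- (d - plan$defoci[[i]][1L]) / plan$step  # 0-based plane position
    idx <- ceiling(q - 0.5) + 1                  # nearest; ties to lower index
    out[, , i] <- pmin(pmax(as.integer(idx), 1L), plan$n[i])
  }
  out
}
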
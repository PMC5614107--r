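#' Specification of a synthetic phantom
#'
#' Describes a phantom by its physical extent and a list of disc primitives
#' (the package's synthetic validation slice is a 1065 nm x 1065 nm xz plane
#' holding three 2.6 nm discs: one at the centre, one at x = 0 / z = 250 nm,
#' one at x = 500 nm / z = 0).
#'
#' @param extent_nm Physical extent `c(x, z)` in nm.
#' @param pixel_size Pixel size in Angstrom.
#' @param discs Data frame with columns `x_nm`, `z_nm` (centre offsets from
#'   the volume centre), `diameter_nm` and `intensity`.
#' @param grid_scale Integer >= 1: coarsen the grid by this factor (pixel
#'   size multiplied, dimensions divided) for fast runs; 1 is full scale.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent_nm = c(1065, 1065), pixel_size = 2.6,
                         discs = three_disc_table(), grid_scale = 1) {
  if (length(extent_nm) != 2L || any(extent_nm <= 0))
    stop("`extent_nm` must be two positive numbers (x, z)", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  need <- c("x_nm", "z_nm", "diameter_nm", "intensity")
  if (!all(need %in% names(discs)))
    stop("`discs` needs columns x_nm, z_nm, diameter_nm, intensity", call. = FALSE)
  if (any(abs(discs$x_nm) + discs$diameter_nm / 2 > extent_nm[1L] / 2) ||
      any(abs(discs$z_nm) + discs$diameter_nm / 2 > extent_nm[2L] / 2))
    stop("a disc lies outside the phantom extent", call. = FALSE)
  structure(list(extent_nm = extent_nm,
                 pixel_size = pixel_size * grid_scale,
                 discs = discs),
            class = "phantom_spec")
}

#' The default three-disc table
#'
#' @return Data frame of the three standard disc positions (nm from centre),
#'   each 2.6 nm in diameter, unit intensity.
#' @export
three_disc_table <- function() {
  data.frame(x_nm = c(0, 0, 500), z_nm = c(0, 250, 0),
             diameter_nm = 2.6, intensity = 1)
}

#' Rasterise a disc phantom
#'
#' Produces a `(nx, 1, nz)` volume: each pixel whose centre lies within a
#' disc gets that disc's intensity (binary-intensity rasterisation). Grid
#' dimensions are `round(extent * 10 / pixel_size)` per axis.
#'
#' @param spec A [phantom_spec()].
#' @return A [tomo_volume()] with `ny = 1`.
#' @export
make_disc_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  px <- spec$pixel_size
  nx <- as.integer(round(spec$extent_nm[1L] * 10 / px))
  nz <- as.integer(round(spec$extent_nm[2L] * 10 / px))
  xc <- centered_coords(nx) * px / 10  # nm
  zc <- centered_coords(nz) * px / 10
  slab <- matrix(0, nx, nz)
  for (i in seq_len(nrow(spec$discs))) {
    d <- spec$discs[i, ]
    r2 <- (d$diameter_nm / 2)^2
    inside <- outer((xc - d$x_nm)^2, (zc - d$z_nm)^2, "+") <= r2
    slab[inside] <- d$intensity
  }
  tomo_volume(slab, px, list(phantom = "discs"))
}

#' Default geometry for the synthetic validation experiment
#'
#' Tilt range -60..+60 degrees in 3 degree steps (41 projections), 4000 nm
#' underfocus at the volume centre, dimensions taken from the phantom.
#'
#' @param phantom A [tomo_volume()] (typically from [make_disc_phantom()]).
#' @param tilt_angles Tilt angles in degrees.
#' @param center_defocus Nominal defocus at the volume centre (nm,
#'   underfocus positive).
#' @return A [tilt_geometry()].
#' @export
default_sim_geometry <- function(phantom,
                                 tilt_angles = seq(-60, 60, by = 3),
                                 center_defocus = 4000) {
  tilt_geometry(dim(phantom), attr(phantom, "pixel_size"),
                tilt_angles, center_defocus)
}

#' Project a volume into a tilt series, with optional depth-dependent CTF
#'
#' For every tilt angle the beam path through the volume is partitioned into
#' slabs perpendicular to the beam. Each slab is projected by the transpose
#' of the back-projection kernel (line integrals with linear interpolation
#' along x); if CTF simulation is requested, each slab's projection is
#' modulated in frequency space by the CTF at the slab centre's defocus, so
#' both the gradient across the tilted image and the gradient through the
#' thickness are present in the simulated data. The slab projections are
#' summed into the tilt image. `ctf = NULL` yields pure projections (the
#' CTF-free control).
#'
#' @param phantom A [tomo_volume()].
#' @param geom A [tilt_geometry()] whose dimensions match the phantom.
#' @param ctf A [ctf_params()] (its defocus is taken per slab from the
#'   geometry) or NULL for no CTF.
#' @param slab_nm Slab thickness in nm (default 20); clamped to one pixel
#'   with a warning if thinner.
#' @param noise_sd Standard deviation of optional additive white Gaussian
#'   noise (image units; default 0 = none).
#' @param seed Seed for the noise generator (only used if `noise_sd > 0`).
#' @return A [tilt_series()] of `length(geom$tilt_angles)` images of size
#'   `(nx, ny)`.
#' @export
project_tilt_series <- function(phantom, geom, ctf = NULL, slab_nm = 20,
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geom, "tilt_geometry"))
  v <- unclass_volume(phantom)
  if (!identical(dim(v), as.integer(geom$dim)) &&
      !identical(as.integer(dim(v)), as.integer(geom$dim)))
    stop("phantom dimensions do not match the geometry", call. = FALSE)
  nx <- geom$dim[1L]; ny <- geom$dim[2L]; nz <- geom$dim[3L]
  px <- geom$pixel_size
  slab_px <- slab_nm * 10 / px
  if (slab_px < 1) {
    warning("slab thinner than one pixel; clamped to one pixel")
    slab_px <- 1
  }
  xc <- centered_coords(nx)
  zc <- centered_coords(nz)
  icen <- floor(nx / 2) + 1L
  # reorder (nx, ny, nz) -> rows over the (x, z) grid, columns over y
  vflat <- aperm(v, c(1L, 3L, 2L))
  dim(vflat) <- c(nx * nz, ny)
  ntilt <- length(geom$tilt_angles)
  out <- array(0, c(nx, ny, ntilt))
  for (i in seq_len(ntilt)) {
    a <- geom$tilt_angles[i] * pi / 180
    xs <- if (geom$invert_handedness) -xc else xc
    h <- outer(-xs * sin(a), zc * cos(a), "+")      # height along beam (px)
    p <- outer(xc * cos(a), zc * sin(a), "+") + icen
    h <- as.vector(h); p <- as.vector(p)
    j0 <- floor(p); w1 <- p - j0; w0 <- 1 - w1
    hmin <- min(h)
    slab_id <- floor((h - hmin) / slab_px)
    img <- matrix(0, nx, ny)
    for (s in sort(unique(slab_id))) {
      rows <- which(slab_id == s)
      proj <- matrix(0, nx, ny)
      rl <- rows[j0[rows] >= 1L & j0[rows] <= nx]
      if (length(rl)) {
        contrib <- rowsum(vflat[rl, , drop = FALSE] * w0[rl],
                          group = j0[rl], reorder = FALSE)
        proj[as.integer(rownames(contrib)), ] <-
          proj[as.integer(rownames(contrib)), ] + contrib
      }
      rr <- rows[j0[rows] + 1L >= 1L & j0[rows] + 1L <= nx]
      if (length(rr)) {
        contrib <- rowsum(vflat[rr, , drop = FALSE] * w1[rr],
                          group = j0[rr] + 1L, reorder = FALSE)
        proj[as.integer(rownames(contrib)), ] <-
          proj[as.integer(rownames(contrib)), ] + contrib
      }
      if (!is.null(ctf)) {
        h_c <- hmin + (s + 0.5) * slab_px
        pctf <- ctf
        pctf$defocus <- geom$center_defocus[i] + geom$z_shift - h_c * px * 0.1
        g <- ctf_image(pctf, c(nx, ny), pixel_size = px)
        proj <- Re(stats::fft(stats::fft(proj) * g, inverse = TRUE)) /
          length(proj)
      }
      img <- img + proj
    }
    out[, , i] <- img
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + stats::rnorm(length(out), sd = noise_sd)
  }
  tilt_series(out, geom$tilt_angles, px)
}
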
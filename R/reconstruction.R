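# Extract image i of a stack as a matrix (robust to ny = 1).
.slice2d <- function(arr, i) {
  d <- dim(arr)
  m <- arr[, , i, drop = FALSE]
  dim(m) <- d[1:2]
  m
}

#' Ramp (radial) filter for weighted back projection
#'
#' Filters each image row-wise along x (the direction across the tilt axis)
#' with a weight proportional to |f|: `w(u) = u` for normalised frequency
#' `u = |f|/f_Nyquist <= cutoff`, then a Gaussian falloff
#' `w(u) = cutoff * exp(-((u - cutoff)/falloff)^2 / 2)` beyond the cutoff
#' (`falloff = 0` truncates hard). The zero-frequency weight is
#' `zero_weight` (default 0). In the 3D correction path this filter is
#' applied to the CTF-corrected image variants, before back projection.
#'
#' @param x A real image matrix `(nx, ny)` or a [tilt_series()] (filtered
#'   image by image).
#' @param cutoff Cutoff as a fraction of Nyquist, in (0, 1].
#' @param falloff Gaussian falloff width as a fraction of Nyquist (>= 0).
#' @param zero_weight Weight given to the zero frequency (default 0).
#' @return The filtered object, same shape/class as the input.
#' @export
radial_filter <- function(x, cutoff = 0.35, falloff = 0.05, zero_weight = 0) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  if (falloff < 0) stop("`falloff` must be >= 0", call. = FALSE)
  if (inherits(x, "tilt_series")) {
    out <- x
    for (i in seq_len(dim(x)[3L]))
      out[, , i] <- radial_filter(.slice2d(x, i), cutoff, falloff, zero_weight)
    return(out)
  }
  nx <- nrow(x)
  u <- abs(.fft_freq(nx, 0.5))  # |f| / f_Nyquist
  w <- ifelse(u <= cutoff, u,
              if (falloff > 0) cutoff * exp(-0.5 * ((u - cutoff) / falloff)^2)
              else 0)
  w[1L] <- zero_weight
  Re(stats::mvfft(stats::mvfft(x) * w, inverse = TRUE)) / nx
}

#' A degenerate single-defocus plan (the 2D baseline)
#'
#' One correction defocus per tilt, at the centre defocus: with this plan the
#' 3D reconstruction path reduces exactly to whole-image correction followed
#' by standard weighted back projection.
#'
#' @param geom A [tilt_geometry()] object.
#' @return A `defocus_plan` with one plane per tilt.
#' @export
single_defocus_plan <- function(geom) {
  stopifnot(inherits(geom, "tilt_geometry"))
  structure(list(defoci = as.list(geom$center_defocus + geom$z_shift),
                 n = rep(1L, length(geom$tilt_angles)),
                 step = Inf),
            class = "defocus_plan")
}

# Shared back-projection kernel.
#
# variants: list over tilts; element i is an array (nx_img, ny, n_i) of
#   (corrected, filtered) image variants for tilt i.
# sel: integer array (nx, nz, n_tilts) selecting the variant per voxel
#   column, or NULL for "always variant 1".
# Voxels projecting (partially) outside an image receive no contribution
# from the missing neighbour. Processing is chunked along y; the result is
# independent of the chunk size (each y-column's accumulation sequence is
# identical).
.backproject <- function(variants, sel, geom, normalize = TRUE,
                         y_chunk = Inf) {
  nx <- geom$dim[1L]; ny <- geom$dim[2L]; nz <- geom$dim[3L]
  ntilt <- length(geom$tilt_angles)
  nx_img <- dim(variants[[1L]])[1L]
  xc <- centered_coords(nx)
  zc <- centered_coords(nz)
  icen <- floor(nx_img / 2) + 1L
  vol <- matrix(0, nx * nz, ny)
  y_chunk <- max(1L, min(as.numeric(y_chunk), ny))
  y_starts <- seq.int(1L, ny, by = y_chunk)
  for (ys in y_starts) {
    ycols <- ys:min(ys + y_chunk - 1L, ny)
    acc <- matrix(0, nx * nz, length(ycols))
    for (i in seq_len(ntilt)) {
      a <- geom$tilt_angles[i] * pi / 180
      p <- outer(xc * cos(a), zc * sin(a), "+") + icen
      p <- as.vector(p)
      j0 <- floor(p)
      w1 <- p - j0
      w0 <- 1 - w1
      selvec <- if (is.null(sel)) NULL else as.vector(sel[, , i])
      nvar <- dim(variants[[i]])[3L]
      for (k in seq_len(nvar)) {
        rows <- if (is.null(selvec)) seq_along(p) else which(selvec == k)
        if (!length(rows)) next
        img <- variants[[i]][, ycols, k, drop = FALSE]
        dim(img) <- c(nx_img, length(ycols))
        rl <- rows[j0[rows] >= 1L & j0[rows] <= nx_img]
        if (length(rl))
          acc[rl, ] <- acc[rl, ] + img[j0[rl], , drop = FALSE] * w0[rl]
        rr <- rows[j0[rows] + 1L >= 1L & j0[rows] + 1L <= nx_img]
        if (length(rr))
          acc[rr, ] <- acc[rr, ] + img[j0[rr] + 1L, , drop = FALSE] * w1[rr]
      }
    }
    vol[, ycols] <- acc
  }
  if (normalize) vol <- vol / ntilt
  dim(vol) <- c(nx, nz, ny)
  aperm(vol, c(1L, 3L, 2L))
}

#' Standard weighted back projection
#'
#' Each voxel is projected onto each tilt image
#' (`x_img = x cos(a) + z sin(a)`, y unchanged), the image value is obtained
#' by linear interpolation along x, and the values from all tilt images are
#' added (and divided by the number of tilts). Images are expected to be
#' ramp-filtered already; set `radial = TRUE` to filter here.
#'
#' @param series A [tilt_series()].
#' @param geom A [tilt_geometry()] with matching tilt angles.
#' @param radial Apply [radial_filter()] to the images first (default FALSE:
#'   the caller has filtered them).
#' @param cutoff,falloff Radial-filter parameters, used when `radial = TRUE`.
#' @param normalize Divide by the number of tilts (default TRUE).
#' @param y_chunk Number of xz slices processed at a time; the result is
#'   independent of this value.
#' @return A [tomo_volume()] of dimensions `geom$dim`.
#' @export
wbp_standard <- function(series, geom, radial = FALSE,
                         cutoff = 0.35, falloff = 0.05,
                         normalize = TRUE, y_chunk = Inf) {
  stopifnot(inherits(series, "tilt_series"), inherits(geom, "tilt_geometry"))
  if (dim(series)[3L] != length(geom$tilt_angles))
    stop("series and geometry have different tilt counts", call. = FALSE)
  if (dim(series)[2L] != geom$dim[2L])
    stop("series y dimension must equal the volume's ny", call. = FALSE)
  if (radial) series <- radial_filter(series, cutoff, falloff)
  nximg <- dim(series)[1L]; nyimg <- dim(series)[2L]
  variants <- lapply(seq_len(dim(series)[3L]), function(i) {
    v <- series[, , i, drop = FALSE]
    dim(v) <- c(nximg, nyimg, 1L)
    v
  })
  out <- .backproject(variants, NULL, geom, normalize, y_chunk)
  tomo_volume(out, geom$pixel_size, list(reconstruction = "wbp_standard"))
}

#' Weighted back projection with 3D CTF correction
#'
#' Each tilt image is CTF-corrected at every defocus in the plan (whole-image
#' correction), each corrected variant is ramp-filtered, and during back
#' projection every voxel reads, for each tilt, the variant whose correction
#' defocus is nearest to the voxel's actual defocus at that tilt (via the
#' precomputed defocus-index array). With a single-plane plan this reduces
#' exactly (bit for bit) to correct-then-filter-then-[wbp_standard()].
#'
#' @param series A [tilt_series()] of uncorrected images.
#' @param geom A [tilt_geometry()].
#' @param plan A `defocus_plan` from [plan_defocus_planes()] or
#'   [single_defocus_plan()].
#' @param mode CTF correction mode: `"phaseflip"`, `"multiply"`, `"wiener"`
#'   or `"none"` (no correction; images are only ramp-filtered -- the
#'   CTF-free control).
#' @param ctf A [ctf_params()] carrying voltage, Cs, amplitude contrast and
#'   astigmatism; its defocus field is replaced per plane. Ignored for
#'   `mode = "none"`.
#' @param wiener_constant Wiener constant for `mode = "wiener"`.
#' @param radial Apply the radial filter to the corrected variants
#'   (default TRUE; the 3D path filters after correction).
#' @param cutoff,falloff Radial-filter parameters.
#' @param normalize Divide by the number of tilts.
#' @param y_chunk Number of xz slices held at a time (memory knob; the output
#'   is bit-identical for any value).
#' @return A [tomo_volume()].
#' @export
wbp_3dctf <- function(series, geom, plan,
                      mode = c("phaseflip", "multiply", "wiener", "none"),
                      ctf = NULL, wiener_constant = 0.1,
                      radial = TRUE, cutoff = 0.35, falloff = 0.05,
                      normalize = TRUE, y_chunk = Inf) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "tilt_series"), inherits(geom, "tilt_geometry"),
            inherits(plan, "defocus_plan"))
  ntilt <- dim(series)[3L]
  if (ntilt != length(geom$tilt_angles))
    stop("series and geometry have different tilt counts", call. = FALSE)
  if (length(plan$defoci) != ntilt)
    stop("plan and geometry have different tilt counts", call. = FALSE)
  if (mode != "none" && is.null(ctf))
    stop("`ctf` parameters are required unless mode = \"none\"", call. = FALSE)
  nximg <- dim(series)[1L]; nyimg <- dim(series)[2L]
  px <- attr(series, "pixel_size")
  if (mode == "none") {
    # no correction: every variant would be identical; use one per tilt
    variants <- lapply(seq_len(ntilt), function(i) {
      v <- .slice2d(series, i)
      if (radial) v <- radial_filter(v, cutoff, falloff)
      dim(v) <- c(nximg, nyimg, 1L)
      v
    })
    sel <- NULL
  } else {
    variants <- lapply(seq_len(ntilt), function(i) {
      v <- array(0, c(nximg, nyimg, plan$n[i]))
      for (k in seq_len(plan$n[i])) {
        p <- ctf
        p$defocus <- plan$defoci[[i]][k]
        ci <- correct_image(.slice2d(series, i), p, mode, wiener_constant,
                            pixel_size = px)
        if (radial) ci <- radial_filter(ci, cutoff, falloff)
        v[, , k] <- ci
      }
      v
    })
    sel <- if (all(plan$n == 1L)) NULL else build_defocus_array(geom, plan)
  }
  out <- .backproject(variants, sel, geom, normalize, y_chunk)
  tomo_volume(out, geom$pixel_size,
              list(reconstruction = "wbp_3dctf", mode = mode,
                   defocus_step = plan$step))
}
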
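#' Fourier shell correlation between two volumes
#'
#' Shell-wise normalised correlation of the two Fourier transforms:
#' `FSC(s) = Re(sum A conj(B)) / sqrt(sum |A|^2 sum |B|^2)` over the voxels
#' of shell s. Shells are spherical in absolute frequency with width
#' `shell_width` Fourier voxels (of the largest dimension), from DC up to
#' Nyquist.
#'
#' @param vol_a,vol_b 3D real arrays of equal dimensions (and pixel size, if
#'   `tomo_volume`s).
#' @param shell_width Shell width in Fourier voxels (default 1).
#' @param pixel_size Pixel size in Angstrom (defaults to the volumes').
#' @return An object of class `fsc_curve`: data frame with columns `freq`
#'   (shell centre, 1/A), `fsc` and `n_voxels`.
#' @export
fsc <- function(vol_a, vol_b, shell_width = 1, pixel_size = NULL) {
  a <- unclass_volume(vol_a); b <- unclass_volume(vol_b)
  if (!identical(dim(a), dim(b)))
    stop("volumes have different dimensions", call. = FALSE)
  if (is.null(pixel_size)) pixel_size <- attr(vol_a, "pixel_size")
  if (is.null(pixel_size)) pixel_size <- 1
  pa <- attr(vol_a, "pixel_size"); pb <- attr(vol_b, "pixel_size")
  if (!is.null(pa) && !is.null(pb) && pa != pb)
    stop("volumes have different pixel sizes", call. = FALSE)
  d <- dim(a)
  fa <- stats::fft(a); fb <- stats::fft(b)
  fx <- .fft_freq(d[1L], pixel_size)
  fy <- .fft_freq(d[2L], pixel_size)
  fz <- .fft_freq(d[3L], pixel_size)
  f <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
  fstep <- shell_width / (max(d) * pixel_size)
  fnyq <- 1 / (2 * pixel_size)
  shell <- as.integer(floor(f / fstep + 0.5))
  keep <- f <= fnyq
  shell_f <- shell[keep]
  num <- Re(fa * Conj(fb))[keep]
  aa <- (Mod(fa)^2)[keep]
  bb <- (Mod(fb)^2)[keep]
  sn <- rowsum(num, shell_f)
  sa <- rowsum(aa, shell_f)
  sb <- rowsum(bb, shell_f)
  cnt <- as.vector(table(shell_f))
  s <- as.integer(rownames(sn))
  val <- as.vector(sn) / sqrt(as.vector(sa) * as.vector(sb))
  structure(data.frame(freq = s * fstep, fsc = val, n_voxels = cnt),
            pixel_size = pixel_size,
            class = c("fsc_curve", "data.frame"))
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the frequency where the curve first drops below the
#' threshold, linearly interpolated between the bracketing shells. The
#' customary reporting threshold is 0.143.
#'
#' @param curve An `fsc_curve` from [fsc()].
#' @param threshold Threshold in (0, 1), default 0.143.
#' @return Resolution in Angstrom, or `NA` if the curve never crosses.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  if (!nrow(curve)) stop("empty FSC curve", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  o <- curve[order(curve$freq), ]
  o <- o[o$freq > 0 | seq_len(nrow(o)) == 1L, ]
  below <- which(o$fsc < threshold)
  below <- below[below > 1L]  # ignore the DC shell
  if (!length(below)) return(NA_real_)
  k <- below[1L]
  f0 <- o$freq[k - 1L]; f1 <- o$freq[k]
  v0 <- o$fsc[k - 1L]; v1 <- o$fsc[k]
  fc <- if (v0 == v1) f1 else f0 + (v0 - threshold) / (v0 - v1) * (f1 - f0)
  1 / fc
}

#' Pearson correlation over a spherical neighbourhood
#'
#' Quantifies local recovery of a feature: correlation between a volume and
#' a reference over the voxels within `radius` of `center`, after mean
#' removal (affine-invariant in the volume's intensity scale).
#'
#' @param vol,reference 3D real arrays of equal dimensions.
#' @param center Voxel coordinates `c(x, y, z)` (1-based) of the sphere
#'   centre.
#' @param radius Radius in voxels; the sphere must lie inside both volumes.
#' @return Correlation in `[-1, 1]`, or `NA` if either patch has zero
#'   variance.
#' @export
local_correlation <- function(vol, reference, center, radius) {
  v <- unclass_volume(vol); r <- unclass_volume(reference)
  if (!identical(dim(v), dim(r)))
    stop("volumes have different dimensions", call. = FALSE)
  d <- dim(v)
  full <- d > 1L  # singleton axes (e.g. a 2D xz slice) have no extent
  if (any((center - radius < 1)[full]) || any((center + radius > d)[full]))
    stop("sphere does not fit inside the volumes", call. = FALSE)
  rng <- lapply(1:3, function(k) {
    if (!full[k]) return(center[k])
    (center[k] - radius):(center[k] + radius)
  })
  dist2 <- outer(outer((rng[[1L]] - center[1L])^2,
                       (rng[[2L]] - center[2L])^2, "+"),
                 (rng[[3L]] - center[3L])^2, "+")
  mask <- dist2 <= radius^2
  pv <- v[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE][mask]
  pr <- r[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE][mask]
  if (stats::sd(pv) == 0 || stats::sd(pr) == 0) return(NA_real_)
  stats::cor(pv, pr)
}
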
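#' Microscope and imaging parameters for CTF evaluation
#'
#' Bundles the optical parameters that determine the contrast transfer
#' function (CTF) of a transmission electron microscope. All formulas inside
#' the package work in Angstrom; conversions from the conventional units used
#' here (kV, mm, nm) happen at this boundary.
#'
#' @param defocus Nominal defocus in nm, underfocus positive. With this
#'   convention the CTF has the conventional negative contrast at low
#'   spatial frequency.
#' @param voltage Accelerating voltage in kV.
#' @param cs Spherical aberration in mm.
#' @param amplitude_contrast Dimensionless amplitude contrast A in `[0, 1]`.
#'   The relative phase and amplitude contrasts are derived as
#'   `w1 = sqrt(1 - A^2)` and `w2 = A`.
#' @param defocus_delta Semi-difference of the two astigmatic defoci in nm
#'   (>= 0); 0 disables astigmatism.
#' @param astig_angle Azimuth of the larger-defocus axis in degrees.
#' @param pixel_size Pixel size in Angstrom per pixel (optional here; image
#'   operations that need it accept it explicitly and fall back to this
#'   field).
#'
#' @return An object of class `ctf_params`.
#' @examples
#' p <- ctf_params(defocus = 4000)  # 4 um underfocus, 300 kV defaults
#' ctf_value(p, f = 0)              # equals -A at zero frequency
#' @export
ctf_params <- function(defocus, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.07, defocus_delta = 0,
                       astig_angle = 0, pixel_size = NULL) {
  if (!is.numeric(voltage) || length(voltage) != 1L || voltage <= 0)
    stop("`voltage` must be a single positive number (kV)", call. = FALSE)
  if (!is.numeric(defocus) || length(defocus) != 1L || !is.finite(defocus))
    stop("`defocus` must be a single finite number (nm)", call. = FALSE)
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("`amplitude_contrast` must lie in [0, 1]", call. = FALSE)
  if (defocus_delta < 0)
    stop("`defocus_delta` must be >= 0", call. = FALSE)
  if (!is.null(pixel_size) && pixel_size <= 0)
    stop("`pixel_size` must be positive (Angstrom)", call. = FALSE)
  structure(
    list(voltage = voltage, cs = cs,
         amplitude_contrast = amplitude_contrast,
         defocus = defocus, defocus_delta = defocus_delta,
         astig_angle = astig_angle, pixel_size = pixel_size,
         wavelength = electron_wavelength(voltage)),
    class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf("CTF parameters: %g kV (lambda %.5f A), Cs %g mm, A %.3f\n",
              x$voltage, x$wavelength, x$cs, x$amplitude_contrast))
  cat(sprintf("  defocus %g nm (underfocus positive), astigmatism %g nm @ %g deg\n",
              x$defocus, x$defocus_delta, x$astig_angle))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size %g A\n", x$pixel_size))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' @param voltage Accelerating voltage in kV.
#' @return Wavelength in Angstrom: `12.2639 / sqrt(V * (1 + 0.97845e-6 * V))`
#'   with V in volts, the standard relativistic de Broglie wavelength
#'   `h / sqrt(2 m e V (1 + e V / 2 m c^2))`.
#' @examples
#' electron_wavelength(300)  # ~0.0197 A
#' @export
electron_wavelength <- function(voltage) {
  if (any(!is.finite(voltage)) || any(voltage <= 0))
    stop("`voltage` must be positive (kV)", call. = FALSE)
  v <- voltage * 1000
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

# Effective (astigmatic) defocus in Angstrom at a given azimuth.
.effective_defocus_A <- function(params, azimuth) {
  dz <- params$defocus
  if (params$defocus_delta != 0)
    dz <- dz + params$defocus_delta *
      cos(2 * (azimuth - params$astig_angle) * pi / 180)
  dz * 10  # nm -> A
}

#' Evaluate the CTF at given spatial frequencies
#'
#' Computes `-w1 sin(chi) - w2 cos(chi)` with phase
#' `chi = pi lambda f^2 (dz - 0.5 lambda^2 f^2 Cs)`, where `dz` is the
#' (azimuth-dependent, if astigmatic) defocus. Underfocus-positive defocus
#' gives negative contrast at low frequency.
#'
#' @param params A [ctf_params()] object.
#' @param f Spatial frequency in 1/Angstrom (vectorised, `f >= 0`).
#' @param azimuth Azimuth of the frequency vector in degrees (recycled
#'   against `f`). Ignored when `defocus_delta` is 0.
#' @return CTF values in `[-1, 1]`.
#' @export
ctf_value <- function(params, f, azimuth = 0) {
  stopifnot(inherits(params, "ctf_params"))
  if (any(f < 0)) stop("`f` must be >= 0", call. = FALSE)
  a <- params$amplitude_contrast
  w1 <- sqrt(1 - a^2)
  lam <- params$wavelength
  cs <- params$cs * 1e7  # mm -> A
  dz <- .effective_defocus_A(params, azimuth)
  chi <- pi * lam * f^2 * (dz - 0.5 * lam^2 * f^2 * cs)
  -w1 * sin(chi) - a * cos(chi)
}

# DFT sample frequencies (cycles per Angstrom), zero frequency first,
# matching the layout of stats::fft output.
.fft_freq <- function(n, d) {
  nneg <- floor(n / 2)
  k <- c(seq.int(0L, n - 1L - nneg), if (nneg >= 1L) seq.int(-nneg, -1L))
  k / (n * d)
}

#' CTF sampled on a 2D FFT grid
#'
#' Evaluates the CTF on the discrete frequency grid of an `nx` by `ny` image,
#' with the zero frequency at element (1, 1) (standard DFT layout). The grid
#' is even under point reflection, i.e. the transfer function of a real
#' point-spread function.
#'
#' @param params A [ctf_params()] object.
#' @param dim Image dimensions `c(nx, ny)`; the first index runs across the
#'   tilt axis.
#' @param pixel_size Pixel size in Angstrom; defaults to `params$pixel_size`.
#' @return A real `nx` by `ny` matrix of CTF values.
#' @export
ctf_image <- function(params, dim, pixel_size = params$pixel_size) {
  stopifnot(inherits(params, "ctf_params"))
  if (is.null(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be given and positive", call. = FALSE)
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 1L))
    stop("`dim` must be two positive integers c(nx, ny)", call. = FALSE)
  fx <- .fft_freq(dim[1L], pixel_size)
  fy <- .fft_freq(dim[2L], pixel_size)
  f2 <- outer(fx^2, fy^2, "+")
  f <- sqrt(f2)
  if (params$defocus_delta != 0) {
    az <- atan2(rep(fy, each = dim[1L]), rep(fx, times = dim[2L])) * 180 / pi
    dim(az) <- dim
    g <- ctf_value(params, f, az)
  } else {
    g <- ctf_value(params, f)
  }
  dim(g) <- dim
  g
}

#' Build a frequency-space correction filter from a CTF grid
#'
#' @param ctf_grid Real array of CTF values (any shape).
#' @param mode One of `"phaseflip"` (sign of the CTF, with sign(0) := +1),
#'   `"multiply"` (the CTF itself) or `"wiener"`
#'   (`CTF / (CTF^2 + wiener_constant)`).
#' @param wiener_constant Positive Wiener regularisation constant; only used
#'   for `mode = "wiener"`.
#' @return An array of filter values with the shape of `ctf_grid`.
#' @export
correction_filter <- function(ctf_grid, mode = c("phaseflip", "multiply", "wiener"),
                              wiener_constant = 0.1) {
  mode <- match.arg(mode)
  switch(mode,
    phaseflip = ifelse(ctf_grid >= 0, 1, -1),
    multiply = ctf_grid,
    wiener = {
      if (!is.numeric(wiener_constant) || wiener_constant <= 0)
        stop("`wiener_constant` must be > 0", call. = FALSE)
      ctf_grid / (ctf_grid^2 + wiener_constant)
    })
}

#' CTF-correct a whole image
#'
#' Applies a frequency-space correction filter to the full image (no strips):
#' `result = IFT(FT(image) * filter)`. This is the per-defocus preprocessing
#' step of the 3D correction scheme; the depth dependence of the defocus is
#' handled later, at back-projection time, by choosing among images corrected
#' at different defoci.
#'
#' @param image Real matrix `(nx, ny)`.
#' @inheritParams correction_filter
#' @param params A [ctf_params()] object carrying the defocus to correct at.
#' @param pixel_size Pixel size in Angstrom; defaults to `params$pixel_size`.
#' @return The corrected real image (imaginary residue of the inverse FFT is
#'   discarded).
#' @export
correct_image <- function(image, params, mode = c("phaseflip", "multiply", "wiener"),
                          wiener_constant = 0.1, pixel_size = params$pixel_size) {
  mode <- match.arg(mode)
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(!is.finite(image))) stop("`image` contains non-finite pixels", call. = FALSE)
  g <- ctf_image(params, dim(image), pixel_size)
  filt <- correction_filter(g, mode, wiener_constant)
  Re(stats::fft(stats::fft(image) * filt, inverse = TRUE)) / length(image)
}

#' Strip-based CTF correction of a tilted image (2D baseline)
#'
#' The classical treatment of the defocus gradient across a tilted image:
#' the image is corrected in overlapping strips parallel to the tilt axis
#' (the y axis), each at its local central defocus
#' `defocus(x) = defocus_center + x * pixel_size * sin(tilt) * 0.1` nm
#' (`x` in pixels from the image centre), and the central column of each
#' corrected strip is kept (step of one column, the maximal-accuracy
#' variant). This accounts for the gradient across the image but not for the
#' gradient through the specimen thickness.
#'
#' @param image Real matrix `(nx, ny)`.
#' @param params_center [ctf_params()] with the defocus at the image centre.
#' @param tilt_angle Tilt angle in degrees.
#' @param strip_width Strip width in pixels (default 256); strips at the
#'   image edge are shifted inward so they stay inside the image.
#' @inheritParams correct_image
#' @return The corrected real image.
#' @export
strip_correct_image <- function(image, params_center, tilt_angle,
                                strip_width = 256,
                                mode = c("phaseflip", "multiply", "wiener"),
                                wiener_constant = 0.1,
                                pixel_size = params_center$pixel_size) {
  mode <- match.arg(mode)
  nx <- nrow(image)
  if (strip_width > nx)
    stop("`strip_width` larger than image", call. = FALSE)
  xc <- seq_len(nx) - 1 - floor(nx / 2)
  dloc <- params_center$defocus +
    xc * pixel_size * sin(tilt_angle * pi / 180) * 0.1
  if (max(dloc) == min(dloc))  # no gradient: one whole-image correction
    return(correct_image(image, params_center, mode, wiener_constant, pixel_size))
  if (strip_width == nx) {
    p <- params_center
    out <- correct_image(image, p, mode, wiener_constant, pixel_size)
    return(out)
  }
  out <- matrix(0, nx, ncol(image))
  half <- floor(strip_width / 2)
  for (j in seq_len(nx)) {
    lo <- min(max(j - half, 1L), nx - strip_width + 1L)
    strip <- image[lo:(lo + strip_width - 1L), , drop = FALSE]
    p <- params_center
    p$defocus <- dloc[j]
    cs <- correct_image(strip, p, mode, wiener_constant, pixel_size)
    out[j, ] <- cs[j - lo + 1L, ]
  }
  out
}

#' Reweight a CTF-multiplied average by the summed squared CTFs
#'
#' An average built from CTF-multiplied data is modulated by the summed
#' squared CTFs of its constituents (normalised by the ensemble size, since
#' the average itself carries a 1/N); dividing the Fourier transform by
#' `max(S, floor)` with `S = sum CTF^2 / N` restores the amplitudes and is
#' scale-consistent: duplicating every member leaves the result unchanged.
#' The floor `epsilon * max(S)` guards the division near common zeros.
#'
#' @param volume 3D real array (a `tomo_volume` or plain array).
#' @param params_list List of [ctf_params()], one per contributing CTF.
#' @param pixel_size Pixel size in Angstrom (defaults to the volume's, then
#'   to the first params').
#' @param epsilon Relative floor for the summed squared CTF (default 1e-6).
#' @return The reweighted volume, same class and attributes as the input.
#' @export
reweight_by_summed_ctf2 <- function(volume, params_list,
                                    pixel_size = NULL, epsilon = 1e-6) {
  if (length(params_list) == 0L)
    stop("`params_list` must contain at least one ctf_params", call. = FALSE)
  v <- unclass_volume(volume)
  if (is.null(pixel_size)) pixel_size <- attr(volume, "pixel_size")
  if (is.null(pixel_size)) pixel_size <- params_list[[1L]]$pixel_size
  if (is.null(pixel_size)) stop("`pixel_size` is required", call. = FALSE)
  d <- dim(v)
  fx <- .fft_freq(d[1L], pixel_size)
  fy <- .fft_freq(d[2L], pixel_size)
  fz <- .fft_freq(d[3L], pixel_size)
  f2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  f <- sqrt(f2)
  az <- NULL
  s <- array(0, d)
  for (p in params_list) {
    if (p$defocus_delta != 0) {
      if (is.null(az)) {
        az <- atan2(rep(fy, each = d[1L]), rep(fx, times = d[2L])) * 180 / pi
        az <- array(rep(az, times = d[3L]), d)
      }
      c3 <- ctf_value(p, f, az)
    } else {
      c3 <- ctf_value(p, f)
    }
    s <- s + c3^2
  }
  s <- s / length(params_list)
  floor_val <- epsilon * max(s)
  ft <- stats::fft(v) / pmax(s, floor_val)
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(v)
  restore_volume(out, volume)
}
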
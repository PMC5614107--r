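#' Ensemble of subtomogram positions and tomogram defoci
#'
#' Surrogate for a subtomogram-averaging dataset: z-positions uniform through
#' a slab of the given thickness, nominal tomogram defoci uniform over a
#' defocus range. Both streams (and any later determination error) flow from
#' one seed.
#'
#' @param n Ensemble size (>= 1).
#' @param thickness Tomogram thickness in nm; z is uniform on
#'   `[-thickness/2, thickness/2]`.
#' @param defocus_range Range (nm) of nominal tomogram defoci, default
#'   1500-4500 nm.
#' @param seed Integer seed.
#' @return An object of class `subtomo_ensemble`: data frame with columns
#'   `z` and `defocus` (nm), thickness attached as an attribute.
#' @export
subtomo_ensemble <- function(n, thickness = 160,
                             defocus_range = c(1500, 4500), seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (thickness <= 0) stop("`thickness` must be positive (nm)", call. = FALSE)
  set.seed(seed)
  out <- data.frame(z = stats::runif(n, -thickness / 2, thickness / 2),
                    defocus = stats::runif(n, defocus_range[1L], defocus_range[2L]))
  structure(out, thickness = thickness, seed = seed,
            class = c("subtomo_ensemble", "data.frame"))
}

#' Defocus error of a subtomogram under 2D or 3D correction
#'
#' Under 2D correction the defocus is defined at the tomogram centre, so the
#' error is the distance from the centre to the subtomogram, growing as
#' `1/cos(tilt)` on tilted images. Under 3D correction the defocus is defined
#' at the centre of the nearest defocus step, bounding the error by
#' `step/2` independently of tilt. An optional normally distributed
#' determination error (defocus fitting imprecision) is added to either.
#'
#' @param z Subtomogram z-position(s), nm from the tomogram centre
#'   (vectorised).
#' @param scheme `"2d"` or `"3d"`.
#' @param step Defocus step in nm (required for `"3d"`).
#' @param determination_sd Standard deviation (nm) of the Gaussian defocus
#'   determination error (default 0 = none).
#' @param tilt_angle Tilt angle in degrees (|tilt| < 90); scales the 2D
#'   error by `1/cos(tilt)`; the 3D error is tilt-independent.
#' @param seed Optional seed for the determination error.
#' @return Signed defocus errors in nm.
#' @export
defocus_error <- function(z, scheme = c("2d", "3d"), step = NULL,
                          determination_sd = 0, tilt_angle = 0, seed = NULL) {
  scheme <- match.arg(scheme)
  if (abs(tilt_angle) >= 90)
    stop("`tilt_angle` must satisfy |tilt| < 90 degrees", call. = FALSE)
  if (determination_sd < 0)
    stop("`determination_sd` must be >= 0", call. = FALSE)
  err <- switch(scheme,
    "2d" = z / cos(tilt_angle * pi / 180),
    "3d" = {
      if (is.null(step) || step <= 0)
        stop("`step` must be > 0 (nm) for the 3d scheme", call. = FALSE)
      z - step * round(z / step)
    })
  if (determination_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    err <- err + stats::rnorm(length(z), sd = determination_sd)
  }
  err
}

#' Attenuation caused by phase-flipping at erroneous defocus
#'
#' For each subtomogram the true CTF (at the true, z-dependent defocus) is
#' phase-flipped either correctly or using the erroneous (scheme-dependent)
#' defocus; the curve is the ratio of the summed erroneously flipped CTFs to
#' the summed correctly flipped CTFs:
#' `ratio(f) = sum_i CTF(f; dz_true_i) sign(CTF(f; dz_assumed_i)) /
#'             sum_i |CTF(f; dz_true_i)|`.
#' It equals 1 wherever every error is zero and lies in `[-1, 1]`.
#'
#' @param ensemble A [subtomo_ensemble()].
#' @param ctf_base A [ctf_params()] providing voltage, Cs and amplitude
#'   contrast (its defocus field is unused).
#' @param scheme `"2d"` or `"3d"` (see [defocus_error()]).
#' @param step Defocus step (nm) for the 3d scheme.
#' @param determination_sd Gaussian determination-error SD in nm (default 0).
#' @param freqs Spatial frequency grid in 1/Angstrom; default 256 samples
#'   from 0 to the Nyquist frequency of 2.6 A pixels.
#' @param tilt_angle Tilt angle (degrees) passed to [defocus_error()].
#' @param seed Seed for the determination error; defaults to the ensemble's
#'   seed plus one so positions and errors are reproducible together.
#' @return An object of class `attenuation_curve`: data frame with columns
#'   `freq` (1/A) and `ratio`. Frequencies where the denominator vanishes
#'   get `NA`.
#' @export
attenuation_curve <- function(ensemble, ctf_base, scheme = c("2d", "3d"),
                              step = NULL, determination_sd = 0,
                              freqs = seq(0, 1 / (2 * 2.6), length.out = 256),
                              tilt_angle = 0, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ensemble, "subtomo_ensemble"), inherits(ctf_base, "ctf_params"))
  if (any(freqs < 0)) stop("`freqs` must be >= 0", call. = FALSE)
  if (is.null(seed)) seed <- attr(ensemble, "seed") + 1L
  d_true <- ensemble$defocus - ensemble$z  # higher z -> less underfocus
  err <- defocus_error(ensemble$z, scheme, step, determination_sd,
                       tilt_angle, seed = seed)
  d_assumed <- d_true + err
  ratio <- vapply(freqs, function(f) {
    ct <- ctf_value(ctf_base_at(ctf_base, d_true), f)
    ca <- ctf_value(ctf_base_at(ctf_base, d_assumed), f)
    den <- sum(abs(ct))
    if (den == 0) return(NA_real_)
    sum(ct * ifelse(ca >= 0, 1, -1)) / den  # sign(0) := +1, as in phaseflip
  }, numeric(1))
  structure(data.frame(freq = freqs, ratio = ratio),
            scheme = scheme, step = step,
            determination_sd = determination_sd,
            class = c("attenuation_curve", "data.frame"))
}

# Evaluate-many helper: ctf_value vectorises over f but the defocus lives in
# params; this clone carries a vector defocus through the same formula.
ctf_base_at <- function(params, defocus_nm) {
  p <- params
  p$defocus <- defocus_nm
  p
}

#' Fold gain of 3D over 2D correction at a given resolution
#'
#' Ratio of the two attenuation values at spatial frequency `1/resolution`
#' (curves are linearly interpolated onto that frequency).
#'
#' @param curve_3d,curve_2d [attenuation_curve()] objects (3D and 2D).
#' @param resolution Resolution in Angstrom.
#' @return The 3D/2D attenuation ratio (a fold gain), or `NA` with a warning
#'   when the 2D attenuation is not positive there.
#' @export
fold_gain <- function(curve_3d, curve_2d, resolution = 4.1) {
  f <- 1 / resolution
  v3 <- stats::approx(curve_3d$freq, curve_3d$ratio, xout = f)$y
  v2 <- stats::approx(curve_2d$freq, curve_2d$ratio, xout = f)$y
  if (is.na(v2) || v2 <= 0) {
    warning(sprintf("2D attenuation at %.3g A is not positive (%.3g); fold gain undefined",
                    resolution, v2))
    return(NA_real_)
  }
  v3 / v2
}
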
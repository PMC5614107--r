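test_that("electron wavelength matches the relativistic formula and shrinks with voltage", {
  expect_equal(electron_wavelength(300), 0.0197, tolerance = 2e-3)
  expect_equal(electron_wavelength(100) / electron_wavelength(300), 1.88,
               tolerance = 1e-2)
  v <- c(80, 120, 200, 300, 500)
  expect_true(all(diff(electron_wavelength(v)) < 0))
  expect_error(electron_wavelength(0), "positive")
  expect_error(ctf_params(defocus = 3000, voltage = -5), "voltage")
})

test_that("CTF limits: -A at zero frequency, pure cosine at A = 1", {
  for (A in c(0, 0.07, 0.3, 1)) {
    p <- ctf_params(defocus = 2500, amplitude_contrast = A)
    expect_equal(ctf_value(p, 0), -A)
  }
  p1 <- ctf_params(defocus = 2500, amplitude_contrast = 1)
  f <- seq(0, 0.3, length.out = 50)
  lam <- p1$wavelength
  chi <- pi * lam * f^2 * (25000 - 0.5 * lam^2 * f^2 * 2.7e7)
  expect_equal(ctf_value(p1, f), -cos(chi))
})

test_that("CTF is bounded and azimuth-independent without astigmatism", {
  set.seed(7)
  for (i in 1:20) {
    p <- ctf_params(defocus = runif(1, 500, 6000),
                    voltage = sample(c(120, 200, 300), 1),
                    amplitude_contrast = runif(1))
    f <- runif(40, 0, 0.5)
    v <- ctf_value(p, f, azimuth = runif(40, 0, 360))
    expect_true(all(abs(v) <= 1 + 1e-12))
    expect_equal(v, ctf_value(p, f, azimuth = 0))
  }
})

test_that("astigmatic CTF equals the non-astigmatic CTF at the effective defocus", {
  p <- ctf_params(defocus = 3000, defocus_delta = 200, astig_angle = 30)
  f <- seq(0.01, 0.2, length.out = 25)
  for (az in c(0, 30, 75, 120)) {
    eff <- 3000 + 200 * cos(2 * (az - 30) * pi / 180)
    expect_equal(ctf_value(p, f, azimuth = az),
                 ctf_value(ctf_params(defocus = eff), f))
  }
  expect_error(ctf_params(defocus = 3000, defocus_delta = -1), "defocus_delta")
})

test_that("first zero crossing agrees with an independent bisection oracle", {
  # bracket chosen so only the first zero lies inside
  root <- uniroot(oracle_ctf, c(1e-4, 0.04), defocus_nm = 4000,
                  tol = 1e-12)$root
  p <- ctf_params(defocus = 4000)
  expect_equal(ctf_value(p, root), 0, tolerance = 1e-8)
  eps <- 1e-4
  expect_true(sign(ctf_value(p, root - eps)) != sign(ctf_value(p, root + eps)))
  # analytic first zero (Cs term negligible at this frequency):
  # -w1 sin(chi) - w2 cos(chi) = 0  ->  chi0 = pi - atan(w2 / w1)
  chi0 <- pi - atan(0.07 / sqrt(1 - 0.07^2))
  expect_equal(root, sqrt(chi0 / (pi * p$wavelength * 40000)), tolerance = 1e-3)
})

test_that("ctf_image: DC element, point symmetry, Nyquist sample", {
  p <- ctf_params(defocus = 3200, amplitude_contrast = 0.1, pixel_size = 4)
  for (d in list(c(8, 8), c(9, 7), c(16, 1))) {
    g <- ctf_image(p, d)
    expect_equal(g[1, 1], -0.1)
    # even under point reflection about the DFT origin
    flip <- function(n) c(1, if (n > 1) n:2)
    expect_equal(g, g[flip(d[1]), flip(d[2]), drop = FALSE], ignore_attr = TRUE)
  }
  g <- ctf_image(p, c(16, 8))
  expect_equal(g[9, 1], ctf_value(p, 1 / (2 * 4)))
})

test_that("astigmatic ctf_image varies with azimuth at fixed |f|", {
  p <- ctf_params(defocus = 3000, defocus_delta = 300, pixel_size = 4)
  g <- ctf_image(p, c(32, 32))
  # same |f| along x and y axes, different azimuth
  expect_false(isTRUE(all.equal(g[5, 1], g[1, 5])))
  p0 <- ctf_params(defocus = 3000, pixel_size = 4)
  g0 <- ctf_image(p0, c(32, 32))
  expect_equal(g0[5, 1], g0[1, 5])
})

test_that("correction filters implement phaseflip, multiply and Wiener", {
  p <- ctf_params(defocus = 3000, pixel_size = 5)
  g <- ctf_image(p, c(32, 16))
  pf <- correction_filter(g, "phaseflip")
  expect_true(all(pf %in% c(-1, 1)))
  expect_equal(pf[1, 1], -1)  # DC has CTF = -A < 0
  expect_identical(correction_filter(g, "multiply"), g)
  w <- correction_filter(g, "wiener", wiener_constant = 1e-9)
  sel <- abs(g) > 0.5
  expect_equal(w[sel], 1 / g[sel], tolerance = 1e-7)
  expect_error(correction_filter(g, "nonsense"))
  expect_error(correction_filter(g, "wiener", wiener_constant = 0), "wiener")
})

test_that("phase-flip correction is a bit-level involution", {
  set.seed(1)
  img <- matrix(rnorm(32 * 24), 32, 24)
  p <- ctf_params(defocus = 2800, pixel_size = 3)
  once <- correct_image(img, p, "phaseflip")
  twice <- correct_image(once, p, "phaseflip")
  # sign^2 = 1: the filter applied twice is the identity filter
  g <- ctf_image(p, dim(img))
  s <- correction_filter(g, "phaseflip")
  expect_identical(s * s, matrix(1, 32, 24))
  expect_equal(twice, img, tolerance = 1e-12)
})

test_that("correct_image: constant images, linearity, algebraic inversion", {
  p <- ctf_params(defocus = 3000, amplitude_contrast = 0.07, pixel_size = 4)
  const <- matrix(2.5, 16, 16)
  expect_equal(correct_image(const, p, "phaseflip"), -const, tolerance = 1e-12)
  set.seed(3)
  i1 <- matrix(rnorm(256), 16); i2 <- matrix(rnorm(256), 16)
  lhs <- correct_image(2 * i1 - 3 * i2, p, "multiply")
  rhs <- 2 * correct_image(i1, p, "multiply") - 3 * correct_image(i2, p, "multiply")
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # dividing the FT by the same grid recovers the original away from zeros
  g <- ctf_image(p, c(16, 16))
  mult <- correct_image(i1, p, "multiply")
  rec <- Re(stats::fft(stats::fft(mult) / g, inverse = TRUE)) / 256
  expect_equal(rec, i1, tolerance = 1e-8)
  expect_error(correct_image(matrix(c(NA, 1:15), 4), p, "phaseflip"), "finite")
})

test_that("delta image under multiplication reproduces the CTF point spread", {
  p <- ctf_params(defocus = 3500, pixel_size = 3)
  img <- matrix(0, 16, 16); img[1, 1] <- 1
  out <- correct_image(img, p, "multiply")
  g <- ctf_image(p, c(16, 16))
  psf <- Re(stats::fft(g, inverse = TRUE)) / 256
  expect_equal(out, psf, tolerance = 1e-12)
})

test_that("strip correction degenerates to whole-image correction", {
  set.seed(5)
  img <- matrix(rnorm(24 * 12), 24, 12)
  p <- ctf_params(defocus = 3000, pixel_size = 8)
  expect_equal(strip_correct_image(img, p, tilt_angle = 0, strip_width = 8,
                                   mode = "phaseflip"),
               correct_image(img, p, "phaseflip"))
  expect_equal(strip_correct_image(img, p, tilt_angle = 45, strip_width = 24,
                                   mode = "phaseflip"),
               correct_image(img, p, "phaseflip"))
  expect_error(strip_correct_image(img, p, 45, strip_width = 25,
                                   mode = "phaseflip"), "strip_width")
})

test_that("strip correction matches an independent per-column oracle", {
  # documented contract: each output column j is the j-th column of a
  # whole-strip correction over the width-w window centred on j (clamped at
  # the edges), using the defocus of column j under the tilt gradient
  set.seed(6)
  nx <- 48; ny <- 6; px <- 8; w <- 16
  img <- matrix(rnorm(nx * ny), nx, ny)
  p <- ctf_params(defocus = 4000, pixel_size = px)
  tilt <- 50
  out <- strip_correct_image(img, p, tilt, strip_width = w, mode = "multiply")
  for (j in c(1, 7, 24, 41, 48)) {
    dj <- 4000 + (j - 1 - floor(nx / 2)) * px * sin(tilt * pi / 180) * 0.1
    lo <- min(max(j - w %/% 2, 1), nx - w + 1)
    pj <- ctf_params(defocus = dj, pixel_size = px)
    ref <- correct_image(img[lo:(lo + w - 1), ], pj, "multiply")
    expect_equal(out[j, ], ref[j - lo + 1, ], tolerance = 1e-12)
  }
  # the gradient makes strip output genuinely differ from whole-image output
  expect_gt(max(abs(out - correct_image(img, p, "multiply"))), 1e-3)
})

test_that("summed-CTF^2 reweighting inverts CTF-squared modulation consistently", {
  set.seed(9)
  vol <- tomo_volume(array(rnorm(16^3), c(16, 16, 16)), 4)
  p <- ctf_params(defocus = 3000, pixel_size = 4)
  # forward-modulate by CTF^2, then reweight with the single-member ensemble
  fx <- stats::fft(tomoctf:::unclass_volume(vol))
  d <- dim(vol)
  g3 <- array(0, d)
  fr <- function(n) tomoctf:::.fft_freq(n, 4)
  f3 <- sqrt(outer(outer(fr(16)^2, fr(16)^2, "+"), fr(16)^2, "+"))
  g3[] <- ctf_value(p, f3)
  mod <- tomo_volume(Re(stats::fft(fx * g3^2, inverse = TRUE)) / length(fx), 4)
  rec <- reweight_by_summed_ctf2(mod, list(p))
  s <- g3^2
  ok <- s > 10 * 1e-6 * max(s)
  fr1 <- stats::fft(tomoctf:::unclass_volume(rec))
  expect_equal(fr1[ok], fx[ok], tolerance = 1e-6)
  # duplicating the ensemble changes nothing (scale consistency)
  rec2 <- reweight_by_summed_ctf2(mod, list(p, p))
  expect_equal(tomoctf:::unclass_volume(rec2), tomoctf:::unclass_volume(rec),
               tolerance = 1e-12)
  expect_error(reweight_by_summed_ctf2(mod, list()), "at least one")
})

test_that("reweighting an ensemble with interleaved zeros stays finite", {
  set.seed(10)
  vol <- tomo_volume(array(rnorm(12^3), c(12, 12, 12)), 4)
  ens <- lapply(c(2000, 2600, 3300, 4100), function(d)
    ctf_params(defocus = d, pixel_size = 4))
  out <- reweight_by_summed_ctf2(vol, ens)
  expect_true(all(is.finite(out)))
})
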
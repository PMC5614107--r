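test_that("radial filter kills DC and weights sinusoids by their frequency", {
  const <- matrix(3, 32, 8)
  out <- radial_filter(const, cutoff = 0.35, falloff = 0.05)
  expect_equal(max(abs(out)), 0, tolerance = 1e-12)
  # pure sinusoid along x at f0, cutoff 1 / falloff 0: scaled by f0/f_Nyq
  nx <- 64
  for (k in c(2, 7, 16)) {
    img <- matrix(sin(2 * pi * k * (0:(nx - 1)) / nx), nx, 4)
    out <- radial_filter(img, cutoff = 1, falloff = 0)
    expect_equal(out, img * (k / (nx / 2)), tolerance = 1e-10)
  }
  expect_error(radial_filter(const, cutoff = 0), "cutoff")
  expect_error(radial_filter(const, cutoff = 2), "cutoff")
})

test_that("radial filter of a delta row equals the transform of the window", {
  nx <- 48
  img <- matrix(0, nx, 1); img[1, 1] <- 1
  cutoff <- 0.5; falloff <- 0.1
  out <- radial_filter(img, cutoff, falloff)
  # independent construction of the designed window
  u <- abs(tomoctf:::.fft_freq(nx, 0.5))
  w <- ifelse(u <= cutoff, u, cutoff * exp(-0.5 * ((u - cutoff) / falloff)^2))
  w[1] <- 0
  expect_equal(out[, 1], Re(stats::fft(w, inverse = TRUE)) / nx,
               tolerance = 1e-12)
})

test_that("a single untilted image back-projects into constant-z columns", {
  set.seed(21)
  img <- matrix(rnorm(12 * 5), 12, 5)
  ser <- tilt_series(array(img, c(12, 5, 1)), 0, 4)
  geom <- tilt_geometry(c(12, 5, 7), 4, 0, 3000)
  vol <- wbp_standard(ser, geom)
  for (z in 1:7) expect_equal(vol[, , z], img, ignore_attr = TRUE)
})

test_that("projector + WBP localise a point to within one voxel", {
  n <- 64
  ph <- array(0, c(n, 1, n))
  ph[ix_center(9, n), 1, ix_center(-5, n)] <- 1
  ph <- tomo_volume(ph, 10)
  geom <- tilt_geometry(c(n, 1, n), 10, seq(-60, 60, 3), 3000)
  ser <- project_tilt_series(ph, geom, ctf = NULL)
  vol <- wbp_standard(ser, geom, radial = TRUE, cutoff = 1, falloff = 0)
  peak <- arrayInd(which.max(vol), dim(vol))
  expect_lte(max(abs(peak - c(ix_center(9, n), 1, ix_center(-5, n)))), 1)
})

test_that("back projection is linear in the tilt series", {
  fx <- small_series()
  s2 <- small_series(seed = 43)
  comb <- fx$series
  comb[] <- 2 * fx$series + 5 * s2$series
  v <- wbp_standard(comb, fx$geom, radial = TRUE)
  v1 <- wbp_standard(fx$series, fx$geom, radial = TRUE)
  v2 <- wbp_standard(s2$series, fx$geom, radial = TRUE)
  expect_equal(tomoctf:::unclass_volume(v),
               2 * tomoctf:::unclass_volume(v1) + 5 * tomoctf:::unclass_volume(v2),
               tolerance = 1e-10)
})

test_that("y-chunked processing is bit-identical to whole-volume processing", {
  fx <- small_series(nx = 20, ny = 7, nz = 12)
  plan <- plan_defocus_planes(fx$geom, 3)
  expect_true(any(plan$n > 1))
  ref <- wbp_3dctf(fx$series, fx$geom, plan, mode = "phaseflip", ctf = fx$ctf)
  for (chunk in c(1, 2, 3, 5)) {
    v <- wbp_3dctf(fx$series, fx$geom, plan, mode = "phaseflip", ctf = fx$ctf,
                   y_chunk = chunk)
    expect_identical(tomoctf:::unclass_volume(v), tomoctf:::unclass_volume(ref))
  }
  r2 <- wbp_standard(fx$series, fx$geom, radial = TRUE)
  c2 <- wbp_standard(fx$series, fx$geom, radial = TRUE, y_chunk = 2)
  expect_identical(tomoctf:::unclass_volume(c2), tomoctf:::unclass_volume(r2))
})

test_that("a single-plane plan reproduces correct-filter-backproject bit for bit", {
  fx <- small_series(nx = 24, ny = 6, nz = 10)
  v3 <- wbp_3dctf(fx$series, fx$geom, single_defocus_plan(fx$geom),
                  mode = "phaseflip", ctf = fx$ctf)
  corrected <- fx$series
  for (i in seq_len(dim(fx$series)[3])) {
    p <- fx$ctf
    p$defocus <- fx$geom$center_defocus[i]
    corrected[, , i] <- correct_image(fx$series[, , i], p, "phaseflip")
  }
  ref <- wbp_standard(corrected, fx$geom, radial = TRUE)
  expect_identical(tomoctf:::unclass_volume(v3), tomoctf:::unclass_volume(ref))
})

test_that("with correction disabled the 3D and 2D paths coincide", {
  fx <- small_series(nx = 18, ny = 3, nz = 14)
  plan <- plan_defocus_planes(fx$geom, 2)
  v_none <- wbp_3dctf(fx$series, fx$geom, plan, mode = "none")
  v_std <- wbp_standard(fx$series, fx$geom, radial = TRUE)
  expect_identical(tomoctf:::unclass_volume(v_none),
                   tomoctf:::unclass_volume(v_std))
})

test_that("a centro-symmetric phantom reconstructs centro-symmetrically", {
  n <- 33  # odd: the centred grid maps onto itself under point reflection
  set.seed(31)
  half <- array(rnorm(n * n), c(n, 1, n))
  ph <- half + half[n:1, 1, n:1, drop = FALSE]
  ph <- tomo_volume(ph, 8)
  geom <- tilt_geometry(c(n, 1, n), 8, seq(-60, 60, 15), 3000)
  ser <- project_tilt_series(ph, geom, ctf = NULL)
  vol <- tomoctf:::unclass_volume(wbp_standard(ser, geom, radial = TRUE))
  expect_equal(vol, vol[n:1, 1, n:1, drop = FALSE], tolerance = 1e-9)
})

test_that("dimension mismatches are rejected", {
  fx <- small_series()
  bad_geom <- tilt_geometry(c(16, 5, 8), 5, fx$geom$tilt_angles, 3000)
  expect_error(wbp_standard(fx$series, bad_geom), "y dimension")
  g2 <- tilt_geometry(c(16, 4, 8), 5, c(0, 10), 3000)
  expect_error(wbp_standard(fx$series, g2), "tilt counts")
  expect_error(wbp_3dctf(fx$series, fx$geom, single_defocus_plan(fx$geom),
                         mode = "phaseflip"), "ctf")
})
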
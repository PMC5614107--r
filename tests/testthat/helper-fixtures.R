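# Shared fixtures and independent oracles for the test suite.

# centred coordinate -> 1-based index (centre voxel at floor(n/2)+1)
ix_center <- function(c, n) c + floor(n / 2) + 1

# Independent re-statement of the oscillating transfer function used as a
# root-finding oracle: written out directly, never calling the package.
oracle_ctf <- function(f, defocus_nm, voltage_kv = 300, cs_mm = 2.7, A = 0.07) {
  v <- voltage_kv * 1000
  lam <- 12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
  dz <- defocus_nm * 10
  cs <- cs_mm * 1e7
  chi <- pi * lam * f^2 * (dz - 0.5 * lam^2 * f^2 * cs)
  -sqrt(1 - A^2) * sin(chi) - A * cos(chi)
}

# A small geometry with a matching random tilt series.
small_series <- function(nx = 16, ny = 4, nz = 8, angles = seq(-60, 60, 30),
                         defocus = 3000, pixel = 5, seed = 42) {
  set.seed(seed)
  geom <- tilt_geometry(c(nx, ny, nz), pixel, angles, defocus)
  data <- array(rnorm(nx * ny * length(angles)), c(nx, ny, length(angles)))
  list(geom = geom,
       series = tilt_series(data, angles, pixel),
       ctf = ctf_params(defocus = defocus, pixel_size = pixel))
}

# The worked-example geometry: tilts 0 and 60 degrees, a 20 nm step, spans
# chosen so both tilts get exactly 7 correction planes, and voxels at the
# positions whose defoci are d-Delta / d-Delta / d+Delta at 0 degrees and
# d-2Delta / d-Delta / d+2Delta at 60 degrees (blue/green/red).
fig1_fixture <- function(d = 3000, step = 20) {
  geom <- tilt_geometry(c(72, 1, 128), 10, c(0, 60), d)  # 1 voxel = 1 nm
  plan <- plan_defocus_planes(geom, step)
  u <- step  # voxels whose height equals one defocus step
  list(geom = geom, plan = plan, step = step, d = d,
       voxels = list(blue = c(round(-sqrt(3) * u), u),
                     green = c(round(-u / sqrt(3)), u),
                     red = c(round(sqrt(3) * u), -u)))
}
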
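# Scalar diffraction engine: angular-spectrum propagation against
# closed-form and brute-force oracles, energy/unitarity invariants, and
# the scaled (chirp-z) focal-plane route.

lam <- 543.5e-6  # mm

gaussian_field <- function(n, window, w0, tilt_cyc = 0) {
  p <- window / n
  x <- ((0:(n - 1)) - n / 2) * p
  A <- exp(-outer(x^2, x^2, `+`) / w0^2) *
    exp(2i * pi * outer(x * tilt_cyc, x * 0, `+`))
  complex_field(A, p)
}

test_that("zero-distance propagation is the identity", {
  f <- gaussian_field(64, 2, 0.3)
  g <- propagate_angular_spectrum(f, 0)
  expect_identical(g$amp, f$amp)
  expect_error(propagate_angular_spectrum(f, NaN), "finite")
})

test_that("free-space spreading follows the Gaussian-beam law within 1%", {
  w0 <- 0.5; N <- 512; window <- 4
  f0 <- gaussian_field(N, window, w0)
  z <- 200
  fz <- propagate_angular_spectrum(f0, z)
  prof <- field_intensity(fz)[, N / 2 + 1]
  x <- field_axis(fz, 1)
  pk <- max(prof); tgt <- pk * exp(-2)
  idx <- which(prof[(N / 2 + 1):N] < tgt)[1] + N / 2
  frac <- (prof[idx - 1] - tgt) / (prof[idx - 1] - prof[idx])
  w_est <- x[idx - 1] + frac * fz$pitch
  w_theory <- w0 * sqrt(1 + (z * lam / (pi * w0^2))^2)
  expect_lt(abs(w_est - w_theory) / w_theory, 0.01)
})

test_that("propagation is unitary and never gains power", {
  f0 <- gaussian_field(256, 3, 0.4)
  fz <- propagate_angular_spectrum(f0, 80)
  fb <- propagate_angular_spectrum(fz, -80)
  expect_lt(max(Mod(fb$amp - f0$amp)) / max(Mod(f0$amp)), 1e-6)
  expect_lte(field_power(fz), field_power(f0) * (1 + 1e-12))
  # hard-edged beam: band limit may only remove power
  fa <- apply_aperture(f0, 1.5, soft_edge = FALSE)
  expect_lte(field_power(propagate_angular_spectrum(fa, 40)),
             field_power(fa) * (1 + 1e-12))
})

test_that("ASM matches a brute-force Rayleigh-Sommerfeld integral", {
  # band-limited input on a 64x64 grid so that both the sampled transfer
  # function and the Riemann-summed RS-I kernel represent the true field
  N <- 64; W <- 0.8; p <- W / N
  f0 <- gaussian_field(N, W, 0.1, tilt_cyc = 3)
  d <- 20
  fa <- propagate_angular_spectrum(f0, d)
  x <- field_axis(f0, 1)
  k <- 2 * pi / lam
  U2 <- matrix(0i, N, N)
  for (j in 1:N) for (l in 1:N) {
    r <- sqrt(outer((x[j] - x)^2, (x[l] - x)^2, `+`) + d^2)
    K <- (d / (1i * lam)) * exp(1i * k * r) / r^2 * (1 - 1 / (1i * k * r))
    U2[j, l] <- sum(f0$amp * K) * p^2
  }
  expect_lt(max(Mod(fa$amp - U2)) / max(Mod(U2)), 1e-3)
})

test_that("scaled propagation degenerates to plain ASM at unit scale", {
  f0 <- gaussian_field(256, 1.5, 0.2)
  g1 <- propagate_angular_spectrum(f0, 100)
  g2 <- propagate_scaled(f0, 100, output_pitch = f0$pitch)
  expect_lt(max(Mod(g1$amp - g2$amp)) / max(Mod(g1$amp)), 1e-3)
})

test_that("chirp-z focal route reproduces the Airy pattern", {
  N <- 512
  f0 <- complex_field(matrix(1 + 0i, N, N), 1.5 / N)
  f0 <- apply_aperture(f0, 1)
  p_in <- field_power(f0)
  f0$vergence <- 1 / 50               # ideal thin lens, f = 50 mm
  ff <- propagate_scaled(f0, 50, output_pitch = 1e-3)
  expect_lte(field_power(ff), p_in * (1 + 1e-9))
  prof <- field_intensity(ff)[, N / 2 + 1]
  ctr <- N / 2 + 1
  dmin <- which(diff(prof[ctr:N]) > 0)[1]
  r0 <- (dmin - 1) * 1e-3
  expect_lt(abs(r0 - 1.22 * lam * 50 / 1), 1e-3)  # within one sample
  # peak matches the closed-form uniform-disk focal intensity P*A/(lam*f)^2
  expect_lt(abs(max(prof) - p_in * pi * 0.5^2 / (lam * 50)^2) /
              (p_in * pi * 0.5^2 / (lam * 50)^2), 0.01)
})

test_that("vergence-referenced transfer route matches direct ASM", {
  N <- 512; p <- 1.5 / N
  x <- ((0:(N - 1)) - N / 2) * p
  A <- exp(-outer(x^2, x^2, `+`) / 0.2^2)
  V <- 1 / 80
  chirp <- exp(-1i * pi * V * outer(x^2, x^2, `+`) / lam)
  full <- propagate_angular_spectrum(complex_field(A * chirp, p), 30)
  env <- propagate_layered(complex_field(A, p, vergence = V), 30, 1)
  expect_equal(env$pitch, p * (1 - 30 * V))
  expect_equal(env$vergence, V / (1 - 30 * V))
  Ie <- field_intensity(env)[, N / 2 + 1]
  If <- field_intensity(full)[, N / 2 + 1]
  Ifi <- stats::approx(x, If, xout = x * (1 - 30 * V))$y
  ok <- abs(x * (1 - 30 * V)) < 0.5
  expect_lt(max(abs(Ie[ok] - Ifi[ok])) / max(If), 1e-3)
})

test_that("apertures clip geometrically and translate covariantly", {
  N <- 256
  f <- complex_field(matrix(1 + 0i, N, N), 2 / N)
  # larger than the grid diagonal: unchanged
  expect_identical(apply_aperture(f, 10)$amp, f$amp)
  # transmitted power equals the geometric area fraction
  g <- apply_aperture(f, 1, soft_edge = FALSE)
  expect_lt(abs(field_power(g) / field_power(f) - pi * 0.5^2 / 4),
            pi * 1 * (2 / N) / 4)   # one edge ring of pixels
  # translation covariance
  g0 <- apply_aperture(f, 0.8)
  g1 <- apply_aperture(f, 0.8, center = c(1, 0))
  shift <- round(1 / f$pitch)
  expect_equal(g1$amp[(1 + shift):N, ], g0$amp[1:(N - shift), ],
               tolerance = 1e-12)
})

test_that("phase masks change phase only and validate their grid", {
  f <- gaussian_field(128, 2, 0.4)
  z <- matrix(0, 128, 128)
  expect_equal(apply_phase_mask(f, z)$amp, f$amp)
  gc <- apply_phase_mask(f, z + 0.123)
  expect_equal(Mod(gc$amp), Mod(f$amp), tolerance = 1e-12)
  expect_error(apply_phase_mask(f, matrix(0, 64, 64)), "congruent")
  # a thin-lens mask focuses: on-axis intensity is maximal near z = f
  N <- 256; fl <- 60
  pw <- complex_field(matrix(1 + 0i, N, N), 3 / N)
  pw <- apply_aperture(pw, 2)
  x <- field_axis(pw, 1)
  opd_um <- -outer(x^2, x^2, `+`) / (2 * fl) * 1e3
  lensed <- apply_phase_mask(pw, opd_um, to_reference_power = 1 / fl)
  onax <- vapply(c(0.8, 0.9, 1, 1.1, 1.2) * fl, function(z) {
    g <- propagate_scaled(lensed, z, output_pitch = 2e-3, n_out = 64)
    field_intensity(g)[33, 33]
  }, 0)
  expect_equal(which.max(onax), 3L)
})

test_that("field snapshots export to TIFF with a metadata sidecar", {
  f <- gaussian_field(64, 2, 0.3)
  paths <- write_field_tiff(f, file.path(tempdir(), "snap"))
  expect_true(all(file.exists(paths)))
  img <- tiff::readTIFF(paths[1])
  expect_equal(dim(img), c(64, 64))
  expect_equal(max(img), 1, tolerance = 1e-6)
  meta <- readLines(paths[4])
  expect_true(any(grepl("wavelength_nm: 543.5", meta)))
})
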
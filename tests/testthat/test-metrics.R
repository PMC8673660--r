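# Image-quality metrics: Zernike fits, Strehl, MTF, and the coherent vs
# geometric image simulations.

test_that("Zernike fits round-trip single-mode injections to 1%", {
  n <- 96
  u <- ((0:(n - 1)) - n / 2) / (n / 2 - 4)
  PX <- matrix(u, n, n); PY <- matrix(u, n, n, byrow = TRUE)
  disk <- PX^2 + PY^2 <= 1
  modes <- iolbench:::zernike_modes(6)
  for (i in seq_len(nrow(modes))) {
    if (modes$n[i] == 0) next
    W <- matrix(NA_real_, n, n)
    W[disk] <- 0.1 * iolbench:::zernike_poly(modes$n[i], modes$m[i],
                                             PX[disk], PY[disk])
    fit <- zernike_fit(opd_map(W, 2 / n, 2 * (n / 2 - 4) / (n / 2)),
                       aperture_diameter = 2 * (n / 2 - 4) * (2 / n),
                       max_order = 8)
    expect_lt(abs(zernike_coef(fit, modes$n[i], modes$m[i]) - 0.1), 0.001)
    others <- fit$coefficient[!(fit$n == modes$n[i] & fit$m == modes$m[i])]
    expect_lt(max(abs(others)), 0.001)
  }
  # null map fits to all zeros
  W0 <- matrix(0, n, n); W0[!disk] <- NA
  f0 <- zernike_fit(opd_map(W0, 2 / n, 2), aperture_diameter = 1.8,
                    max_order = 6)
  expect_lt(max(abs(f0$coefficient)), 1e-12)
})

test_that("Strehl of a PSF against itself is 1, with pitch guarded", {
  psf <- list(intensity = matrix(runif(64^2), 64), pitch = 1e-4)
  expect_equal(strehl(psf, psf), 1)
  bad <- psf; bad$pitch <- 2e-4
  expect_error(strehl(psf, bad), "pitch")
})

test_that("MTF normalization and diffraction-limited closed form hold", {
  bench <- cached_bench()
  ref <- cached_ref_psf(512)
  m <- mtf_from_psf(ref$intensity, ref$pitch)
  expect_equal(m$mtf_x[1], 1)
  expect_equal(m$mtf_y[1], 1)
  expect_true(all(m$mtf <= 1 + 1e-9))
  # incoherent diffraction-limited MTF of a circular pupil
  Rf <- system_opd(bench)$aperture_diameter / 2
  s <- iolbench:::seg_iol_to_z(bench, bench$screen_z, from = "front_vertex")
  zeta <- sum(s$t / s$n)
  fc <- 2 * Rf / (543.5e-6 * zeta)
  phi <- acos(pmin(m$freq / fc, 1))
  mth <- (2 / pi) * (phi - cos(phi) * sin(phi))
  sel <- m$freq <= 0.8 * fc
  expect_lt(max(abs(m$mtf_x[sel] - mth[sel])), 0.02)
})

test_that("aligned field and ray MTF curves agree within 0.05", {
  bench <- cached_bench()
  psf <- compute_field_psf(bench, samples = 512, n_out = 256)
  rp <- ray_psf(bench, output_pitch = psf$pitch, n_out = 256)
  mf <- mtf_from_psf(psf$intensity, psf$pitch)
  mr <- mtf_from_psf(rp$psf, psf$pitch)
  sel <- mf$freq <= 100
  expect_lt(max(abs(mf$mtf_x[sel] - mr$mtf_x[sel])), 0.05)
  expect_lt(max(abs(mf$mtf_y[sel] - mr$mtf_y[sel])), 0.05)
})

test_that("aligned PSF is symmetric and misaligned PSFs are skewed", {
  bench <- cached_bench()
  psf <- compute_field_psf(bench, samples = 512, n_out = 256)
  I <- psf$intensity; n <- nrow(I)
  expect_lt(max(abs(I - I[c(1, n:2), c(1, n:2)])) / max(I), 0.01)

  # decentration crushes the spot along y: centroid follows the
  # ray-predicted image point, opposite poses mirror (engine consistency)
  pd <- compute_field_psf(set_misalignment(bench, 800, 0), samples = 512,
                          n_out = 256)
  cen <- raster_centroid(pd$intensity, pd$pitch)
  abs_y <- pd$center[2] + cen[2]
  ray_y <- iolbench:::ray_image_centroid(set_misalignment(bench, 800, 0))[2]
  expect_lt(abs(abs_y - ray_y), 0.01)
  expect_gt(abs(ray_y), 0.05)   # the spot moves visibly off axis

  # tilt disperses the spot along x: strong x-skew, mirrored for -tilt
  pt <- compute_field_psf(set_misalignment(bench, 0, 8), samples = 512,
                          n_out = 256)
  skew <- function(I, pitch) {
    x <- ((0:(nrow(I) - 1)) - nrow(I) %/% 2) * pitch
    w <- rowSums(I) / sum(I)
    mu <- sum(w * x); s2 <- sum(w * (x - mu)^2)
    sum(w * (x - mu)^3) / s2^1.5
  }
  sk <- skew(pt$intensity, pt$pitch)
  expect_gt(abs(sk), 0.3)
  pt2 <- compute_field_psf(set_misalignment(bench, 0, -8), samples = 512,
                           n_out = 256)
  expect_lt(abs(skew(pt2$intensity, pt2$pitch) + sk), 0.05)
})

test_that("coherent imaging shows fringes in the bars; ray imaging none", {
  bench <- cached_bench()
  tg <- generate_usaf_target(extent = 2.0, samples = 512, groups = 3)
  im <- simulate_image(bench, tg, engine = "field", samples = 1024,
                       n_out = 512)
  ir <- simulate_image(bench, tg, engine = "ray", n_out = 512,
                       output_pitch = im$pitch)
  ideal <- iolbench:::resample_mask(tg, im$pitch / abs(im$magnification),
                                    512, invert = im$magnification < 0)
  interior <- erode_mask(ideal > 0.999, 3)
  vf <- im$image[interior]; vr <- ir$image[interior]
  mod_f <- (max(vf) - min(vf)) / (max(vf) + min(vf))
  mod_r <- (max(vr) - min(vr)) / (max(vr) + min(vr))
  expect_gt(mod_f, 0.2)     # interference fringes inside the white bars
  expect_lt(mod_r, 0.05)    # geometric image is smooth inside the bars
  .cache$images <- list(im = im, ir = ir, ideal = ideal, tg = tg)
})

test_that("decentration blurs the image and tilt blurs it asymmetrically", {
  bench <- cached_bench()
  tg <- .cache$images$tg
  e0 <- edge_widths(.cache$images$im$image)
  expect_lt(abs(e0["rise"] - e0["fall"]), 0.5)  # aligned: symmetric edges

  sharp <- function(img) max(abs(diff(img))) / max(img)
  imd <- simulate_image(set_misalignment(bench, 800, 0), tg,
                        engine = "field", samples = 1024, n_out = 512,
                        output_pitch = .cache$images$im$pitch)
  expect_lt(sharp(imd$image), 0.6 * sharp(.cache$images$im$image))

  # tilt widens all edges, and the bar sides nearer the tilted IOL
  # surface are more smeared: the comet-like PSF makes rising and falling
  # edges (along x) unequally wide, flipping with the tilt sign
  imt <- simulate_image(set_misalignment(bench, 0, 8), tg,
                        engine = "field", samples = 1024, n_out = 512,
                        output_pitch = .cache$images$im$pitch)
  imt2 <- simulate_image(set_misalignment(bench, 0, -8), tg,
                         engine = "field", samples = 1024, n_out = 512,
                         output_pitch = .cache$images$im$pitch)
  ep <- edge_widths(imt$image); en <- edge_widths(imt2$image)
  expect_gt(mean(ep), mean(e0) * 1.2)
  dp <- ep["rise"] - ep["fall"]; dn <- en["rise"] - en["fall"]
  expect_lt(dp * dn, 0)                       # asymmetry flips with tilt
})
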
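# Conic/aspheric geometry, exact refraction and thin-element OPD maps.

test_that("conic sag matches exact closed forms", {
  s <- conic_surface(7.814, 0)
  expect_identical(sag(s, 0, 0), 0)
  # sphere: exact circular sag
  expect_equal(sag(s, 3, 0), 7.814 - sqrt(7.814^2 - 9), tolerance = 1e-12)
  # paraboloid: r^2 / (2R) exactly
  p <- conic_surface(10, -1)
  r <- seq(0, 8, by = 0.5)
  expect_equal(sag(p, r, 0), r^2 / 20, tolerance = 1e-14)
  # domain violation reports the largest valid radius
  sph <- conic_surface(5, 0, semi_aperture = 4.9)
  expect_error(sag(sph, 5.2, 0), "max valid r")
})

test_that("refraction satisfies Snell's law exactly", {
  # plane interface at 30 degrees: arcsin(sin(30)/1.5)
  r <- make_ray(c(0, 0, -1), c(sin(pi / 6), 0, cos(pi / 6)))
  r2 <- refract_ray(r, conic_surface(Inf, semi_aperture = 10), 0, 1, 1.5)
  expect_equal(asin(r2$direction[1]) * 180 / pi,
               asin(sin(pi / 6) / 1.5) * 180 / pi, tolerance = 1e-10)
  # normal incidence leaves the direction unchanged
  r3 <- refract_ray(make_ray(c(0, 0, -1), c(0, 0, 1)),
                    conic_surface(12, -0.3), 0, 1, 1.47)
  expect_equal(r3$direction, c(0, 0, 1), tolerance = 1e-12)

  # property: n1 sin(i) = n2 sin(t) for 1e4 random rays on a conic
  set.seed(7)
  n <- 1e4
  surf <- conic_surface(15, -0.4, a4 = 1e-5, semi_aperture = 6)
  th <- runif(n, 0, 2 * pi); rr <- sqrt(runif(n)) * 5
  ux <- runif(n, -0.2, 0.2); uy <- runif(n, -0.2, 0.2)
  b <- ray_bundle(rr * cos(th), rr * sin(th), rep(-3, n),
                  ux, uy, sqrt(1 - ux^2 - uy^2), px = rep(0, n),
                  py = rep(0, n))
  d1 <- cbind(b$dx, b$dy, b$dz)
  b2 <- iolbench:::bundle_refract(b, surf, 0, 1, 1.47)
  al <- b2$alive
  sl <- iolbench:::sag_slope(surf, sqrt(b2$x^2 + b2$y^2))
  nr <- cbind(-sl * b2$x / sqrt(b2$x^2 + b2$y^2),
              -sl * b2$y / sqrt(b2$x^2 + b2$y^2), 1)
  nr <- nr / sqrt(rowSums(nr^2))
  d2 <- cbind(b2$dx, b2$dy, b2$dz)
  sin1 <- sqrt(pmax(1 - rowSums(d1 * nr)^2, 0))
  sin2 <- sqrt(pmax(1 - rowSums(d2 * nr)^2, 0))
  expect_lt(max(abs(1 * sin1 - 1.47 * sin2)[al]), 1e-12)
})

test_that("rays that miss or exceed the critical angle are flagged", {
  r <- make_ray(c(8, 0, -1), c(0, 0, 1))
  r2 <- refract_ray(r, conic_surface(12, 0, semi_aperture = 5), 0, 1, 1.5)
  expect_false(r2$alive)
  expect_identical(r2$fate, "escaped")
  # TIR: steep ray from dense to rare medium at a plane interface
  ang <- 50 * pi / 180
  r3 <- refract_ray(make_ray(c(0, 0, -1), c(sin(ang), 0, cos(ang))),
                    conic_surface(Inf, semi_aperture = 10), 0, 1.5, 1)
  expect_false(r3$alive)
  expect_identical(r3$fate, "tir")
})

make_iol <- function(decenter = 0, tilt = 0) {
  lens_element(conic_surface(13.37, a4 = -2.5e-3, semi_aperture = 3.4),
               conic_surface(-13.37, semi_aperture = 3.4),
               center_thickness = 0.9, material_index = 1.47,
               decenter_y = decenter, tilt_y = tilt)
}

test_that("element OPD maps obey plate, translation and thin-lens limits", {
  # plane-parallel plate: constant map (piston removed at the centre)
  plate <- lens_element(conic_surface(Inf, semi_aperture = 6),
                        conic_surface(Inf, semi_aperture = 6),
                        1, 1.5195)
  m <- element_opd_map(plate, 64, 0.15, 1.336)
  v <- m$opd[!is.na(m$opd)]
  expect_lt(max(abs(v)), 1e-12)
  # tilted plate: still constant (chord t / cos(theta))
  plate$tilt_y <- 8
  mt <- element_opd_map(plate, 64, 0.15, 1.336)
  expect_lt(max(abs(mt$opd[!is.na(mt$opd)])), 1e-9)

  # decentration translates the aligned map by d along y
  el0 <- make_iol(); el1 <- make_iol(decenter = 300)  # um
  pitch <- 0.1
  m0 <- element_opd_map(el0, 80, pitch, 1.336)
  m1 <- element_opd_map(el1, 80, pitch, 1.336)
  k <- round(0.3 / pitch)
  a <- m1$opd[, (1 + k):80]; b <- m0$opd[, 1:(80 - k)]
  ok <- !is.na(a) & !is.na(b)
  d <- (a - b)[ok]
  d <- d - mean(d)                  # maps are pistonless at their centres
  expect_lt(max(abs(d)), 1e-6)

  # unposed map is rotationally symmetric
  expect_lt(max(abs(m0$opd - t(m0$opd)), na.rm = TRUE), 1e-9)

  # paraxial-zone quadratic matches the element's thin power within 0.5%
  el <- make_iol()
  mm <- element_opd_map(el, 256, 0.005, 1.336)
  ax <- ((0:255) - 128) * 0.005
  R2 <- outer(ax^2, ax^2, `+`)
  sel <- R2 < 0.5^2
  cf <- stats::lm.fit(cbind(1, R2[sel], R2[sel]^2),
                      mm$opd[sel] * 1e-3)$coefficients
  P_thin <- (1.47 - 1.336) * (1 / 13.37 + 1 / 13.37)
  expect_lt(abs(-2 * cf[2] - P_thin) / P_thin, 0.005)
})

test_that("chord map agrees with the two per-surface screens when aligned", {
  el <- make_iol()
  pitch <- 0.02; n <- 256
  m <- element_opd_map(el, n, pitch, 1.336)
  s1 <- iolbench:::posed_surface_screen(el, "front", n, pitch, 1.336, 1.47)
  s2 <- iolbench:::posed_surface_screen(el, "back", n, pitch, 1.47, 1.336)
  d <- m$opd - (s1$opd + s2$opd)
  lam_um <- 543.5e-3
  expect_lt(stats::sd(d[!is.na(d)]), lam_um / 50)
})

test_that("pose envelope and element invariants are enforced", {
  expect_error(make_iol(decenter = 2500), "envelope")
  expect_error(make_iol(tilt = 20), "envelope")
  expect_error(lens_element(conic_surface(10), conic_surface(-10), -1, 1.47),
               "positive")
  expect_equal(paraxial_power(
    lens_element(conic_surface(Inf, semi_aperture = 6),
                 conic_surface(Inf, semi_aperture = 6), 1, 1.5), 1.336), 0)
})
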
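# Bench assembly, calibrations and focal-plane search.

test_that("the default bench realizes the stated optical prescription", {
  bench <- cached_bench()
  # cornea: 43 D into aqueous by construction of the apex radius
  Pc <- (1.336 - 1) / bench$cornea$surface$radius * 1000
  expect_equal(Pc, 43, tolerance = 1e-9)
  expect_equal(bench$iol$material_index, 1.47)
  expect_equal(bench$stop$diameter, 9.072)
  # empty pose
  expect_equal(bench$iol$decenter_y, 0)
  expect_equal(bench$iol$tilt_y, 0)
  # conic recalibrated within +/-0.05 of the nominal -0.26
  expect_lt(abs(bench$cornea$surface$conic - (-0.26)), 0.05)
})

test_that("stop calibration yields a 5-mm pupil, matching matrix optics", {
  bench <- cached_bench()
  expect_equal(bench$pupil_diameter, 5, tolerance = 1e-6)
  # independent 2x2 transfer-matrix computation of the marginal-ray
  # height at the IOL plane: translation (reduced) and refraction blocks
  Pc <- 0.043
  segs <- rbind(c(2.5, 1.336), c(1.0, 1.5195),
                c(bench$iol$axial_position - bench$cornea$z - 3.5, 1.336))
  M <- diag(2)
  for (i in seq_len(nrow(segs)))
    M <- matrix(c(1, 0, segs[i, 1] / segs[i, 2], 1), 2) %*% M
  M <- M %*% matrix(c(1, -Pc, 0, 1), 2)
  h <- (M %*% c(bench$stop$diameter / 2, 0))[1]
  expect_equal(2 * h, bench$pupil_diameter, tolerance = 1e-6)
})

test_that("the calibrated IOL has 20 D in water by two routes", {
  bench <- cached_bench()
  expect_equal(paraxial_power(bench$iol, 1.336), 20, tolerance = 0.1)
  # two-ray paraxial trace through the actual surfaces
  h <- 1e-5
  b <- ray_bundle(h, 0, -5, 0, 0, 1, 0, 0)
  b <- iolbench:::bundle_through_element(b, bench$iol, 1.336)
  # exit reduced slope of a collimated paraxial ray: u-bar = -h * P
  expect_equal(-1.336 * b$dx / h * 1000, 20, tolerance = 0.1)
})

test_that("asphere calibration nulls Z(4,0) and a spherical IOL cannot", {
  bench <- cached_bench()
  expect_lt(abs(bench$provenance$z40_residual_um), 0.005)
  sph <- bench
  sph$iol$front$a4 <- 0
  z40 <- zernike_coef(zernike_fit(system_opd(sph), max_order = 8), 4, 0)
  expect_gt(z40, 0)   # spherical IOL leaves positive SA on the cornea's
})

test_that("focal-plane search is deterministic and physically placed", {
  bench <- cached_bench()
  z1 <- find_focal_plane(bench, samples = 256)
  z2 <- find_focal_plane(bench, samples = 256,
                         bracket = z1 + c(-0.27, 0.31))
  expect_lt(abs(z1 - z2), 2e-3)
  # the aberration-free reference focuses at its paraxial image distance
  zi <- find_focal_plane(bench, samples = 256, ideal = TRUE)
  zp <- iolbench:::ray_paraxial_focus(set_misalignment(bench, 0, 0))
  expect_lt(abs(zi - zp), 0.01)
  # the aberrated bench's best focus sits within its residual-SA shift
  expect_lt(abs(bench$screen_z - zp), 0.06)
  expect_error(find_focal_plane(bench, samples = 256,
                                bracket = bench$iol$axial_position + c(1, 2)),
               "wet-cell")
})

test_that("misalignment poses apply to the IOL only, within the envelope", {
  bench <- cached_bench()
  b0 <- set_misalignment(bench, 0, 0)
  expect_identical(b0, bench)
  bd <- set_misalignment(bench, 800, 0)
  expect_equal(bd$iol$decenter_y, 800)
  expect_identical(bd$screen_z, bench$screen_z)
  expect_identical(bd$cornea, bench$cornea)
  expect_error(set_misalignment(bench, 2500, 0), "envelope")
  expect_error(set_misalignment(bench, 0, 16), "envelope")
})

test_that("opposite decentrations give mirror PSFs and equal Strehl", {
  bench <- cached_bench()
  ref <- cached_ref_psf(256)
  pp <- compute_field_psf(set_misalignment(bench, 300, 0), samples = 256)
  pm <- compute_field_psf(set_misalignment(bench, -300, 0), samples = 256)
  expect_equal(pp$center[2], -pm$center[2], tolerance = 1e-6)
  s1 <- strehl(pp, ref); s2 <- strehl(pm, ref)
  expect_lt(abs(s1 - s2), 1e-3)
  # mirror the -d PSF about the x axis: identical intensity pattern
  n <- ncol(pm$intensity)
  expect_lt(max(abs(pp$intensity - pm$intensity[, c(1, n:2)])) /
              max(pp$intensity), 0.02)
})

test_that("configurations round-trip through their YAML file format", {
  cfg <- default_bench_config()
  cfg$pose$decenter_y <- 250
  path <- tempfile(fileext = ".yaml")
  write_bench_config(cfg, path)
  cfg2 <- read_bench_config(path)
  expect_equal(cfg2$pose$decenter_y, 250)
  expect_equal(cfg2$grid$window, cfg$grid$window, tolerance = 1e-9)
  expect_equal(unlist(cfg2$media), unlist(cfg$media))
  expect_error(build_bench(utils::modifyList(cfg, list(target_pupil = 10))),
               "config")
})

test_that("bench provenance records the resolved geometry", {
  bench <- cached_bench()
  path <- tempfile(fileext = ".txt")
  write_provenance(bench, path)
  lines <- readLines(path)
  expect_true(any(grepl("^cornea_iol_mm:", lines)))
  expect_true(any(grepl("^iol_a4:", lines)))
  expect_true(any(grepl("^screen_z:", lines)))
})
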
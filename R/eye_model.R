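# Model-eye bench of the simulated IOL test setup:
#   collimated source -> USAF target (at infinity through an ideal
#   collimator) -> aperture stop -> aspheric cornea (air/aqueous) ->
#   wet cell (water, two plane BK7 windows) -> posed IOL -> screen.
#
# All unprinted distances are derived by calibration: the stop sits at the
# cornea's front focal plane, the cornea->IOL spacing realizes the 5-mm
# pupil on the IOL, the IOL asphere nulls the system spherical aberration,
# and the screen sits at the aligned focal plane.

#' Default bench configuration
#'
#' All tunables of the simulated bench, serializable to YAML through
#' [write_bench_config()]. Distances not fixed here are resolved by the
#' calibrations in [build_bench()] and recorded in the bench provenance.
#'
#' @return a nested list of configuration values.
#' @export
default_bench_config <- function() {
  list(
    wavelength = 543.5,                  # nm, monochromatic coherent source
    media = list(air = 1.0, aqueous = 1.336, bk7 = 1.5195, iol = 1.47),
    stop = list(diameter = 9.072),       # mm
    cornea = list(K = 43, conic = -0.26, semi_aperture = 5.0,
                  pin_sa = TRUE, target_z40 = 0.172, sa_zone = 6.0),
    target_pupil = 5.0,                  # mm beam footprint on the IOL
    iol = list(power = 20, thickness = 0.9, semi_aperture = 3.4,
               a4 = NULL, a6 = 0),
    plates = list(thickness = 1.0, cornea_gap = 2.5, iol_gap = 2.5),
    collimator_f = 100,                  # mm, target presented at infinity
    grid = list(n = 1024, window = 13.608),
    pose = list(decenter_y = 0, tilt_y = 0),
    sweeps = list(decenter = seq(0, 800, by = 100),
                  tilt = seq(0, 8, by = 2)),
    seed = 0)
}

#' Read / write a bench configuration
#'
#' Plain-text hierarchical (YAML) round-trip of the configuration list.
#'
#' @param path file path.
#' @return `read_bench_config`: the configuration list.
#' @export
read_bench_config <- function(path) yaml::read_yaml(path)

#' @rdname read_bench_config
#' @param config a configuration list.
#' @export
write_bench_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}

#' Assemble and calibrate the model-eye bench
#'
#' Builds the element train from a configuration:
#' * cornea: single aspheric refracting surface air->aqueous with apex
#'   radius `(n_aq - n_air) / K` (43 D -> 7.814 mm at n_aq = 1.336) and the
#'   configured conic constant; if `cornea$pin_sa` is TRUE the conic is
#'   recalibrated (within +/-0.05 of the configured value) so the corneal
#'   wavefront Z(4,0) over the `sa_zone` equals `target_z40`.
#' * wet cell: two plane BK7 windows flanking the IOL, water elsewhere.
#' * IOL: equal-radii biconvex lens (index from `media$iol`) whose radii
#'   give the configured paraxial power in water, with the front-surface
#'   a4 calibrated to null the aligned bench's exit-pupil Z(4,0).
#' * geometry: stop at the cornea's front focal plane; cornea->IOL spacing
#'   set so the stop produces the configured pupil on the IOL.
#'
#' The screen position is left unset; call [find_focal_plane()] /
#' [focus_bench()].
#'
#' @param config configuration list, see [default_bench_config()].
#' @param calibrate_sa logical; skip the (slower) IOL asphere calibration
#'   when FALSE and `config$iol$a4` is given.
#' @return an object of class `model_eye_bench`.
#' @export
build_bench <- function(config = default_bench_config(),
                        calibrate_sa = TRUE) {
  cfg <- utils::modifyList(default_bench_config(), config)
  med <- cfg$media
  bad <- c(if (cfg$stop$diameter <= 0) "stop.diameter",
           if (cfg$cornea$K <= 0) "cornea.K",
           if (cfg$iol$power <= 0) "iol.power",
           if (cfg$target_pupil <= 0 ||
               cfg$target_pupil >= cfg$stop$diameter) "target_pupil",
           if (cfg$grid$n < 64) "grid.n")
  if (length(bad)) stop("inconsistent config keys: ", paste(bad, collapse = ", "))

  Pc <- cfg$cornea$K / 1000              # 1/mm
  cornea_radius <- (med$aqueous - med$air) / Pc
  conic <- cfg$cornea$conic
  cornea <- conic_surface(cornea_radius, conic,
                          semi_aperture = cfg$cornea$semi_aperture)
  if (isTRUE(cfg$cornea$pin_sa)) {
    conic <- calibrate_cornea_conic(cornea_radius, conic, med$aqueous,
                                    zone = cfg$cornea$sa_zone,
                                    target = cfg$cornea$target_z40)
    cornea <- conic_surface(cornea_radius, conic,
                            semi_aperture = cfg$cornea$semi_aperture)
  }

  # equal-radii biconvex IOL with the configured thick-lens power in water
  R_iol <- iol_radius_for_power(cfg$iol$power / 1000, cfg$iol$thickness,
                                med$iol, med$aqueous)

  stop_z <- 0
  cornea_z <- stop_z + med$air / Pc       # stop at the front focal plane
  bench <- structure(list(
    wavelength = cfg$wavelength, media = med,
    stop = list(z = stop_z, diameter = cfg$stop$diameter),
    cornea = list(surface = cornea, z = cornea_z, power = Pc),
    iol = NULL, plate1 = NULL, plate2 = NULL,
    screen_z = NULL, pupil_diameter = NA_real_,
    collimator_f = cfg$collimator_f, grid = cfg$grid,
    config = cfg, provenance = list()), class = "model_eye_bench")

  bench <- calibrate_stop_to_pupil(bench, cfg$target_pupil,
                                   R_iol = R_iol)
  if (calibrate_sa && is.null(cfg$iol$a4)) {
    bench <- calibrate_iol_asphere(bench)
  } else if (!is.null(cfg$iol$a4)) {
    bench$iol$front$a4 <- cfg$iol$a4
  }
  bench <- set_misalignment(bench, cfg$pose$decenter_y, cfg$pose$tilt_y)
  bench
}

#' @export
print.model_eye_bench <- function(x, ...) {
  cat("<model_eye_bench>\n")
  cat(sprintf("  lambda %.1f nm | stop %.3f mm at z=%.3f | cornea R %.4f mm Q %.4f at z=%.3f\n",
              x$wavelength, x$stop$diameter, x$stop$z,
              x$cornea$surface$radius, x$cornea$surface$conic, x$cornea$z))
  cat(sprintf("  IOL R %+.4f/%+.4f mm, a4 %.4g, t %.2f mm, n %.3f at z=%.4f (pupil %.3f mm)\n",
              x$iol$front$radius, x$iol$back$radius, x$iol$front$a4,
              x$iol$center_thickness, x$iol$material_index,
              x$iol$axial_position, x$pupil_diameter))
  cat(sprintf("  pose: decenter %g um, tilt %g deg | screen_z %s\n",
              x$iol$decenter_y, x$iol$tilt_y,
              if (is.null(x$screen_z)) "unset" else sprintf("%.4f mm", x$screen_z)))
  invisible(x)
}

# radius of the equal-radii biconvex lens giving thick-lens power P (1/mm)
iol_radius_for_power <- function(P, t, n_lens, n_med) {
  dn <- n_lens - n_med
  p1 <- (n_lens / t) * (1 - sqrt(1 - P * t / n_lens))  # surface power, 1/mm
  dn / p1
}

#' Calibrate the stop/pupil geometry
#'
#' Places the IOL at the axial position where the paraxial footprint of the
#' 9.072-mm stop's collimated marginal ray equals the target pupil
#' diameter (matrix optics through cornea and front wet-cell window), and
#' verifies the result by an independent paraxial marginal-ray trace
#' through the exact surfaces. The stop itself sits at the cornea's front
#' focal plane (telecentric image space), ahead of the cornea.
#'
#' @param bench a `model_eye_bench` under construction.
#' @param target_pupil pupil diameter on the IOL in mm.
#' @param R_iol IOL surface radius (from the power calibration).
#' @return the bench with IOL, windows and provenance set.
#' @export
calibrate_stop_to_pupil <- function(bench, target_pupil = 5,
                                    R_iol = bench$iol$front$radius) {
  cfg <- bench$config
  med <- bench$media
  Pc <- bench$cornea$power
  tp <- cfg$plates$thickness
  g1 <- cfg$plates$cornea_gap
  # reduced distance cornea -> IOL needed for footprint ratio m = D_p/D_s
  zeta_t <- (1 - target_pupil / bench$stop$diameter) / Pc
  d2 <- (zeta_t - g1 / med$aqueous - tp / med$bk7) * med$aqueous + g1 + tp
  if (d2 <= g1 + tp + cfg$iol$thickness)
    stop("no physical IOL position: stop must precede cornea and ",
         "the wet-cell window must fit before the IOL")
  iol_z <- bench$cornea$z + d2
  plane <- function(sa) conic_surface(Inf, semi_aperture = sa)
  iol_sa <- cfg$iol$semi_aperture
  bench$iol <- lens_element(
    front = conic_surface(+R_iol, a4 = 0, a6 = cfg$iol$a6,
                          semi_aperture = iol_sa),
    back = conic_surface(-R_iol, semi_aperture = iol_sa),
    center_thickness = cfg$iol$thickness, material_index = med$iol,
    axial_position = iol_z)
  bench$plate1 <- lens_element(plane(6), plane(6), tp, med$bk7,
                               axial_position = bench$cornea$z + g1 + tp / 2)
  bench$plate2 <- lens_element(plane(6), plane(6), tp, med$bk7,
                               axial_position = iol_z + cfg$plates$iol_gap +
                                 tp / 2)
  # independent check: paraxial marginal ray traced through the real train
  h <- 1e-4
  b <- trace_marginal(bench, h, to_z = iol_z)
  bench$pupil_diameter <- 2 * b$x / h * (bench$stop$diameter / 2)
  bench$provenance$stop_z <- bench$stop$z
  bench$provenance$cornea_z <- bench$cornea$z
  bench$provenance$iol_z <- iol_z
  bench$provenance$cornea_iol_mm <- d2
  bench$provenance$pupil_on_iol_mm <- bench$pupil_diameter
  bench
}

# paraxial-regime marginal ray: exact trace at tiny height h, stopping at
# the plane to_z (before the IOL surfaces)
trace_marginal <- function(bench, h, to_z) {
  b <- ray_bundle(x = h, y = 0, z = bench$stop$z, dx = 0, dy = 0, dz = 1,
                  px = 1e-9, py = 0)
  b <- bundle_refract(b, bench$cornea$surface, bench$cornea$z,
                      bench$media$air, bench$media$aqueous)
  b <- bundle_through_element(b, bench$plate1, bench$media$aqueous)
  bundle_to_plane(b, to_z, bench$media$aqueous)
}

# ordered refracting events for the ray engine
bench_surface_train <- function(bench) {
  n <- bench$media
  iol_ev <- if (isTRUE(bench$iol_ideal)) {
    # incoming reference focus: paraxial focus of the cornea+window chain,
    # measured from the lens plane
    h <- 1e-6
    bb <- ray_bundle(h, 0, bench$stop$z, 0, 0, 1, 1e-9, 0)
    bb <- bundle_refract(bb, bench$cornea$surface, bench$cornea$z,
                         n$air, n$aqueous)
    bb <- bundle_through_element(bb, bench$plate1, n$aqueous)
    R_in <- (bb$z - bb$x / bb$dx * bb$dz) - bench$iol$axial_position
    list(type = "ideal", P = paraxial_power(bench$iol, n$aqueous) / 1000,
         z = bench$iol$axial_position, n1 = n$aqueous, R_in = R_in)
  } else {
    list(type = "element", element = bench$iol, n1 = n$aqueous,
         n2 = n$aqueous)
  }
  list(
    list(type = "conic", surface = bench$cornea$surface,
         z = bench$cornea$z, n1 = n$air, n2 = n$aqueous),
    list(type = "element", element = bench$plate1,
         n1 = n$aqueous, n2 = n$aqueous),
    iol_ev,
    list(type = "element", element = bench$plate2,
         n1 = n$aqueous, n2 = n$aqueous))
}

# reduced-thickness segment lists for the field engine
seg_cornea_to_iol <- function(bench) {
  cfg <- bench$config
  g1 <- cfg$plates$cornea_gap; tp <- cfg$plates$thickness
  d2 <- bench$iol$axial_position - bench$cornea$z
  list(t = c(g1, tp, d2 - g1 - tp),
       n = c(bench$media$aqueous, bench$media$bk7, bench$media$aqueous))
}

# segments from the IOL back vertex plane (where the field engine leaves
# the lens) to an axial plane z
seg_iol_to_z <- function(bench, z,
                         from = c("front_vertex", "back_vertex", "center")) {
  from <- match.arg(from)
  cfg <- bench$config
  g2 <- cfg$plates$iol_gap; tp <- cfg$plates$thickness
  t2 <- switch(from, front_vertex = -bench$iol$center_thickness / 2,
               back_vertex = bench$iol$center_thickness / 2, center = 0)
  d <- z - bench$iol$axial_position
  if (d <= g2 + tp) stop("plane lies inside the wet-cell window")
  list(t = c(g2 - t2, tp, d - g2 - tp),
       n = c(bench$media$aqueous, bench$media$bk7, bench$media$aqueous))
}

bench_image_zeta <- function(bench, z = bench$screen_z) {
  s <- seg_iol_to_z(bench, z, from = "center")
  sum(s$t / s$n)
}

# thin-element paraxial power of the IOL as the field engine sees it
iol_thin_power <- function(bench) {
  el <- bench$iol
  dn <- el$material_index - bench$media$aqueous
  dn * (1 / el$front$radius - 1 / el$back$radius)
}

#' Apply an IOL misalignment pose
#'
#' Sets the IOL decentration (along y) and tilt (about y) and leaves every
#' other element, including the screen, untouched.
#'
#' @param bench a `model_eye_bench`.
#' @param decenter_y decentration in micrometres (|d| <= 2000).
#' @param tilt_y tilt in degrees (|t| <= 15).
#' @return the posed bench.
#' @export
set_misalignment <- function(bench, decenter_y = 0, tilt_y = 0) {
  check_pose(decenter_y, tilt_y)
  bench$iol$decenter_y <- decenter_y
  bench$iol$tilt_y <- tilt_y
  bench
}

# --- cornea / IOL aberration calibrations ------------------------------

#' Corneal wavefront Z(4,0)
#'
#' Traces a collimated hexagonal-grid bundle over `zone` through the cornea
#' alone into aqueous, references the OPD to a sphere centred on the
#' paraxial focus, and reads the OSA Z(4,0) coefficient.
#'
#' @param surface the cornea `conic_surface`.
#' @param n_aqueous image-space index.
#' @param zone aperture zone diameter in mm.
#' @param n_grid pupil raster size.
#' @return Z(4,0) in micrometres.
#' @export
cornea_z40 <- function(surface, n_aqueous = 1.336, zone = 6, n_grid = 64) {
  Pc <- (n_aqueous - 1) / surface$radius
  g <- grid_pupil(n_grid)
  R <- zone / 2
  b <- ray_bundle(x = g$px * R, y = g$py * R, z = rep(-5, nrow(g)),
                  dx = 0, dy = 0, dz = rep(1, nrow(g)),
                  px = g$px, py = g$py)
  b <- bundle_refract(b, surface, 0, 1, n_aqueous)
  C <- c(0, 0, n_aqueous / Pc)
  om <- exit_pupil_opd(b, C, n_aqueous, pupil_diameter = zone,
                       n_grid = n_grid)
  zernike_coef(zernike_fit(om, max_order = 8), 4, 0)
}

# recalibrate the conic constant (within +/-0.05) so the corneal Z(4,0)
# over the zone matches the target
calibrate_cornea_conic <- function(radius, conic0, n_aqueous, zone, target,
                                   tol = 1e-4) {
  f <- function(q) cornea_z40(conic_surface(radius, q, semi_aperture = 5),
                              n_aqueous, zone) - target
  v0 <- f(conic0)
  if (abs(v0) < tol) return(conic0)
  r <- stats::uniroot(f, c(conic0 - 0.05, conic0 + 0.05), tol = 1e-7)
  r$root
}

# axial reference point of the ray comparator: the plane maximizing the
# pupil-summed coherent intensity (the PSF-peak image point). The aligned
# bundle is traced once and reprojected onto candidate reference centres.
ray_best_focus <- function(bench, n_grid = 64) {
  aligned <- set_misalignment(bench, 0, 0)
  z0 <- ray_paraxial_focus(aligned)
  b <- trace_bundle(aligned, pupil = grid_pupil(n_grid))
  al <- b$alive
  lam0 <- bench$wavelength * 1e-6
  n <- bench$media$aqueous
  peak <- function(cz) {
    proj <- b$opl + n * ((0 - b$x) * b$dx + (0 - b$y) * b$dy +
                           (cz - b$z) * b$dz)
    Mod(sum(exp(-2i * pi * proj[al] / lam0)))^2
  }
  zs <- seq(z0 - 0.2, z0 + 0.2, by = 5e-3)
  best <- zs[which.max(vapply(zs, peak, 0))]
  stats::optimize(peak, best + c(-8e-3, 8e-3), maximum = TRUE)$maximum
}

# reduced axial position where the paraxial marginal ray of the full train
# crosses the axis
ray_paraxial_focus <- function(bench) {
  h <- 1e-4
  b <- ray_bundle(x = h, y = 0, z = bench$stop$z, dx = 0, dy = 0, dz = 1,
                  px = 1e-9, py = 0)
  b <- bundle_through_train(b, bench_surface_train(bench))
  b$z - b$x / b$dx * b$dz
}

# paraxial exit-pupil radius of the aligned bench on a given plane: the
# tiny-height marginal exit ray backtracked to the plane, scaled to the
# full stop
paraxial_pupil_radius <- function(bench, plane_z) {
  h <- 1e-4
  aligned <- set_misalignment(bench, 0, 0)
  b <- ray_bundle(x = h, y = 0, z = bench$stop$z, dx = 0, dy = 0, dz = 1,
                  px = 1e-9, py = 0)
  b <- bundle_through_train(b, bench_surface_train(aligned))
  xc <- b$x + (plane_z - b$z) / b$dz * b$dx
  xc / h * (bench$stop$diameter / 2)
}

#' System exit-pupil OPD of the bench
#'
#' Exact ray trace of the whole (possibly posed) train on a pupil raster;
#' the optical path differences are referenced to a sphere centred on the
#' *aligned* system's paraxial focus (fixed during misalignment sweeps),
#' indexed by exit-ray coordinates on the IOL front-vertex plane, and
#' reported in the clinical OPD-excess convention (positive corneal SA).
#'
#' @param bench a `model_eye_bench`.
#' @param n_grid pupil trace grid (rays per axis).
#' @param center_z reference sphere centre z (mm); default the aligned
#'   paraxial focus.
#' @param raster_n raster size of the returned map (reconstructed from the
#'   order-12 Zernike fit attached as attribute `zernike`).
#' @return an `opd_map` over the exit pupil.
#' @export
system_opd <- function(bench, n_grid = 64, center_z = NULL,
                       raster_n = n_grid) {
  g <- grid_pupil(n_grid)
  b <- trace_bundle(bench, pupil = g)
  aligned <- set_misalignment(bench, 0, 0)
  if (is.null(center_z)) center_z <- ray_paraxial_focus(aligned)
  plane_z <- bench$iol$axial_position - bench$iol$center_thickness / 2
  Rf <- paraxial_pupil_radius(bench, plane_z)
  exit_pupil_opd(b, c(0, 0, center_z), bench$media$aqueous,
                 pupil_diameter = 2 * Rf, n_grid = raster_n,
                 pupil_plane_z = plane_z)
}

#' Exit-pupil diameter mapped from a corneal zone
#'
#' Traces the ray entering the cornea at `cornea_zone/2` and reports twice
#' its exit-pupil crossing radius: the sub-aperture of the system OPD map
#' that corresponds to the given corneal zone (used to express system
#' spherical aberration on the cornea's 6-mm reporting zone).
#'
#' @param bench a `model_eye_bench`.
#' @param cornea_zone corneal zone diameter in mm.
#' @return the mapped exit-pupil zone diameter in mm.
#' @export
mapped_zone_diameter <- function(bench, cornea_zone = 6) {
  r0 <- cornea_zone / 2
  b <- ray_bundle(x = r0, y = 0, z = bench$stop$z, dx = 0, dy = 0, dz = 1,
                  px = r0 / (bench$stop$diameter / 2), py = 0)
  b <- bundle_through_train(b, bench_surface_train(bench))
  plane_z <- bench$iol$axial_position - bench$iol$center_thickness / 2
  2 * abs(b$x + (plane_z - b$z) / b$dz * b$dx)
}

#' Calibrate the IOL front-surface asphere
#'
#' Finds the even-asphere coefficient a4 of the IOL front surface that
#' nulls the aligned bench's exit-pupil Z(4,0) over the full pupil (the
#' spherical-aberration-correcting IOL). The paraxial power is untouched
#' (a4 has no r^2 content).
#'
#' @param bench an assembled `model_eye_bench`.
#' @param tol acceptable residual |Z(4,0)| in um.
#' @return the bench with the calibrated IOL and provenance entries.
#' @export
calibrate_iol_asphere <- function(bench, tol = 5e-3) {
  aligned <- set_misalignment(bench, 0, 0)
  f <- function(a4) {
    aligned$iol$front$a4 <- a4
    zernike_coef(zernike_fit(system_opd(aligned), max_order = 8), 4, 0)
  }
  r <- stats::uniroot(f, c(-8e-3, 2e-3), tol = 1e-10)
  resid <- f(r$root)
  if (abs(resid) > tol)
    stop(sprintf("asphere calibration residual Z(4,0) = %.4g um > %.4g um",
                 resid, tol))
  bench$iol$front$a4 <- r$root
  bench$provenance$iol_a4 <- r$root
  bench$provenance$z40_residual_um <- resid
  bench
}

# --- coherent field pipeline -------------------------------------------

# propagate an input field given at the stop plane through the bench to
# the screen plane z_out (default: bench$screen_z)
field_through_bench <- function(bench, input, output_pitch, n_out = 512,
                                center = c(0, 0), ideal = FALSE,
                                z_out = bench$screen_z) {
  f <- field_to_iol_exit(bench, input, ideal = ideal)
  s <- seg_iol_to_z(bench, z_out)
  propagate_layered(f, s$t, s$n, output_pitch = output_pitch,
                    n_out = n_out, center = center)
}

# stop -> cornea -> wet cell -> IOL, field left at the IOL front-vertex
# plane with its converging reference wave. The analytic reference
# (vergence chain) carries the ideal focusing exactly; the system's
# aberration -- computed once per pose by the exact ray trace of the whole
# train and expressed over exit-pupil coordinates -- is applied to the
# envelope as a single phase screen at the IOL plane (isoplanatic hybrid;
# see the methods vignette). Apertures clip at their physical planes and
# every leg is propagated as a wave, so stop diffraction and coherent
# fringes are fully retained. The ideal bench drops only the aberration
# screen.
field_to_iol_exit <- function(bench, input, ideal = FALSE) {
  med <- bench$media
  el <- bench$iol
  f <- apply_aperture(input, bench$stop$diameter)
  f <- propagate_angular_spectrum(f, bench$cornea$z - bench$stop$z, med$air)
  # cornea: aperture + ideal power (exact paraxial focus of the surface)
  f <- apply_aperture(f, 2 * bench$cornea$surface$semi_aperture)
  h <- 1e-6
  bp <- ray_bundle(h, 0, 0, 0, 0, 1, 0, 0)
  bp <- bundle_refract(bp, bench$cornea$surface, 0, med$air, med$aqueous)
  f$vergence <- med$aqueous / (bp$z - bp$x / bp$dx * bp$dz)
  # wet cell to the IOL front vertex plane (windows as reduced
  # water-equivalent layers; their 4th-order aberration is ~lambda/40 at
  # this NA)
  s1 <- seg_cornea_to_iol(bench)
  s1$t[length(s1$t)] <- s1$t[length(s1$t)] - el$center_thickness / 2
  f <- propagate_layered(f, s1$t, s1$n)
  # IOL plane: aperture (posed), system aberration screen, ideal power
  f <- apply_aperture(f, 2 * el$front$semi_aperture,
                      center = c(0, el$decenter_y * 1e-3))
  plane_z <- el$axial_position - el$center_thickness / 2
  z_ref <- ray_paraxial_focus(set_misalignment(bench, 0, 0))
  if (!ideal) {
    om <- system_opd(bench, n_grid = 64, center_z = z_ref)
    fit <- attr(om, "zernike")
    Rf <- om$aperture_diameter / 2
    x <- field_axis(f, 1); y <- field_axis(f, 2)
    PX <- matrix(x / Rf, length(x), length(y))
    PY <- matrix(y / Rf, length(x), length(y), byrow = TRUE)
    W <- matrix(0, length(x), length(y))
    inside <- PX^2 + PY^2 <= 1.1         # beam stays inside the fit zone
    W[inside] <- zernike_eval(fit, PX[inside], PY[inside])
    # clinical OPD-excess convention -> transmitted phase is its negative
    f <- apply_phase_mask(f, opd_map(-W, f$pitch, 2 * Rf))
  }
  sseg <- seg_iol_to_z(bench, z_ref, from = "front_vertex")
  f$vergence <- 1 / sum(sseg$t / sseg$n)
  f
}

# geometric image centroid at the fixed screen (frames the PSF window)
ray_image_centroid <- function(bench, n_rings = 8) {
  b <- trace_bundle(bench, n_rings = n_rings)
  b <- bundle_to_plane(b, bench$screen_z, bench$media$aqueous)
  c(mean(b$x[b$alive]), mean(b$y[b$alive]))
}

#' Locate the focal plane of the aligned bench
#'
#' With the object mask removed (plane-wave input) the screen is moved
#' along the axis to the plane of maximum on-axis intensity, bracketed
#' around the paraxial image plane and refined by golden-section search to
#' micrometre tolerance. The result is held fixed for all misalignment
#' poses of a sweep.
#'
#' @param bench an assembled `model_eye_bench` (alignment pose is forced).
#' @param samples field grid samples used for the search.
#' @param bracket length-2 axial search interval in mm; default paraxial
#'   focus +/- 1 mm.
#' @param tol axial tolerance in mm.
#' @return the focal-plane z in mm.
#' @export
find_focal_plane <- function(bench, samples = 512, bracket = NULL,
                             tol = 1e-3, ideal = FALSE) {
  aligned <- set_misalignment(bench, 0, 0)
  pw <- generate_plane_wave(samples, bench$grid$window,
                            wavelength = bench$wavelength)
  f <- field_to_iol_exit(aligned, pw, ideal = ideal)
  lam0 <- wavelength_mm(f)
  r2 <- field_radius2(f)
  cfg <- bench$config
  g2 <- cfg$plates$iol_gap; tp <- cfg$plates$thickness
  t2 <- bench$iol$center_thickness / 2
  zeta_of_z <- function(z) {
    (g2 + t2) / bench$media$aqueous + tp / bench$media$bk7 +
      (z - bench$iol$axial_position - g2 - tp) / bench$media$aqueous
  }
  onaxis <- function(z) {
    zeta <- zeta_of_z(z)
    B <- (1 - zeta * f$vergence) / zeta
    S <- sum(f$amp * exp(1i * pi * B * r2 / lam0))
    Mod(S * f$pitch^2 / (lam0 * zeta))^2
  }
  if (is.null(bracket)) {
    V <- f$vergence
    zfoc_red <- 1 / V
    zfoc <- bench$iol$axial_position + g2 + tp +
      (zfoc_red - (g2 + t2) / bench$media$aqueous -
         tp / bench$media$bk7) * bench$media$aqueous
    bracket <- zfoc + c(-0.4, 0.4)
  }
  if (bracket[1] <= bench$iol$axial_position + g2 + tp)
    stop("focal bracket reaches inside the wet-cell window")
  # the axial lobe is only ~2*lambda/NA^2 (~25 um) wide and flanked by
  # side lobes, so a dense scan locates the global peak before the
  # golden-section refinement
  na_red <- bench$pupil_diameter / 2 / (1 / f$vergence)
  step <- max(0.5 * lam0 / na_red^2 * bench$media$aqueous, 2 * tol)
  zs <- seq(bracket[1], bracket[2], by = step)
  Is <- vapply(zs, onaxis, 0)
  k <- which.max(Is)
  if (k == 1L || k == length(zs))
    stop("no interior intensity maximum in the focal bracket")
  gr <- (sqrt(5) - 1) / 2
  a <- zs[k - 1L]; b <- zs[k + 1L]
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- onaxis(c1); fd <- onaxis(d1)
  while (b - a > tol) {
    if (fc > fd) { b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- onaxis(c1)
    } else { a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- onaxis(d1)
    }
  }
  (a + b) / 2
}

#' @rdname find_focal_plane
#' @export
focus_bench <- function(bench, samples = 512) {
  bench$screen_z <- find_focal_plane(bench, samples = samples)
  bench$provenance$screen_z <- bench$screen_z
  bench
}

#' Paraxial magnification from target plane to screen
#'
#' Image height per object height for the infinity-presented target:
#' `-EFL / f_coll`, computed by a paraxial chief-ray trace (negative:
#' the image is inverted).
#'
#' @param bench a focused `model_eye_bench`.
#' @return the lateral magnification (dimensionless).
#' @export
bench_magnification <- function(bench) {
  u <- 1e-6
  b <- ray_bundle(x = 0, y = 0, z = bench$stop$z,
                  dx = sin(u), dy = 0, dz = cos(u), px = 1e-9, py = 0)
  b <- bundle_through_train(b, bench_surface_train(set_misalignment(bench, 0, 0)))
  b <- bundle_to_plane(b, bench$screen_z, bench$media$aqueous)
  -(b$x / u) / bench$collimator_f
}

#' Ray-traced PSF of the bench
#'
#' Exit-pupil OPD by exact ray trace, then the FFT pupil-function PSF
#' ([psf_from_pupil()]). The raster is Strehl-normalized (aberration-free
#' same-pupil peak = 1). The reference sphere is centred on the axial
#' paraxial focus of the aligned system and held fixed for misaligned
#' poses.
#'
#' @param bench a `model_eye_bench`.
#' @param output_pitch image-plane pitch in mm.
#' @param n_out PSF raster size.
#' @param n_grid pupil raster size.
#' @param center_z reference-sphere axial position (default: aligned
#'   paraxial focus).
#' @return list with `psf` (Strehl-referenced intensity), `pitch`,
#'   `strehl`, `opd`.
#' @export
ray_psf <- function(bench, output_pitch, n_out = 256, n_grid = 64,
                    center_z = NULL) {
  if (is.null(center_z))
    center_z <- ray_best_focus(bench)
  sseg <- seg_iol_to_z(bench, center_z, from = "front_vertex")
  zeta <- sum(sseg$t / sseg$n)
  # the pupil raster must sample finely enough that the FFT-PSF replica
  # period exceeds the requested image window
  lam0 <- bench$wavelength * 1e-6
  plane_z <- bench$iol$axial_position - bench$iol$center_thickness / 2
  Rf <- paraxial_pupil_radius(bench, plane_z)
  n_req <- ceiling(2 * Rf * (n_out * output_pitch) / (lam0 * zeta) / 2) * 2
  om <- system_opd(bench, n_grid = n_grid, center_z = center_z,
                   raster_n = max(n_grid, min(n_req, 2048)))
  r <- psf_from_pupil(om, bench$wavelength, image_distance = zeta,
                      n_image = 1, output_pitch = output_pitch,
                      n_out = n_out)
  r$opd <- om
  r
}

#' Write the resolved bench parameters as a provenance block
#'
#' @param bench a `model_eye_bench`.
#' @param path output text file.
#' @return invisibly, the path.
#' @export
write_provenance <- function(bench, path) {
  p <- bench$provenance
  lines <- c(
    sprintf("wavelength_nm: %.6g", bench$wavelength),
    sprintf("stop_diameter_mm: %.6g", bench$stop$diameter),
    sprintf("cornea_radius_mm: %.8g", bench$cornea$surface$radius),
    sprintf("cornea_conic: %.8g", bench$cornea$surface$conic),
    sprintf("iol_radius_mm: %.8g", bench$iol$front$radius),
    sprintf("iol_thickness_mm: %.6g", bench$iol$center_thickness),
    sprintf("iol_index: %.6g", bench$iol$material_index),
    sprintf("media_aqueous: %.6g", bench$media$aqueous),
    sprintf("media_bk7: %.6g", bench$media$bk7),
    sprintf("collimator_f_mm: %.6g", bench$collimator_f),
    vapply(names(p), function(k) sprintf("%s: %.10g", k, p[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}
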
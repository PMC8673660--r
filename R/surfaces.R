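#' Conic/aspheric refracting surface
#'
#' Rotationally symmetric surface with apex radius of curvature, conic
#' constant and even-asphere terms up to r^6:
#' `z(r) = c*r^2 / (1 + sqrt(1 - (1+Q)*c^2*r^2)) + a4*r^4 + a6*r^6`,
#' `c = 1/radius`. Sign convention: light travels +z; positive radius means
#' the centre of curvature lies toward +z.
#'
#' @param radius apex radius of curvature in mm (`Inf` for a plane).
#' @param conic conic constant Q (0 sphere, -1 paraboloid).
#' @param a4,a6 even-asphere coefficients (mm^-3, mm^-5).
#' @param semi_aperture clear semi-aperture in mm.
#' @return an object of class `conic_surface`.
#' @export
conic_surface <- function(radius = Inf, conic = 0, a4 = 0, a6 = 0,
                          semi_aperture = 5) {
  if (radius == 0) stop("radius must be nonzero; use Inf for a plane")
  if (semi_aperture <= 0) stop("semi_aperture must be positive")
  if (is.finite(radius) && conic > -1) {
    rmax <- abs(radius) / sqrt(1 + conic)
    if (semi_aperture > rmax)
      stop(sprintf("sag undefined beyond r = %.4g mm; reduce semi_aperture",
                   rmax))
  }
  structure(list(radius = radius, conic = conic, a4 = a4, a6 = a6,
                 semi_aperture = semi_aperture),
            class = "conic_surface")
}

#' @export
print.conic_surface <- function(x, ...) {
  cat(sprintf(
    "<conic_surface> R %.6g mm, Q %.4g, a4 %.4g, a6 %.4g, semi-ap %.3g mm\n",
    x$radius, x$conic, x$a4, x$a6, x$semi_aperture))
  invisible(x)
}

#' Surface sag
#'
#' @param surface a `conic_surface`.
#' @param x,y transverse coordinates in mm (vectorized, recycled).
#' @return sag z in mm at each point.
#' @export
sag <- function(surface, x, y = 0) {
  r2 <- x^2 + y^2
  s <- surface
  if (is.finite(s$radius)) {
    c0 <- 1 / s$radius
    arg <- 1 - (1 + s$conic) * c0^2 * r2
    if (any(arg <= 0))
      stop(sprintf("sag undefined at r = %.4g mm (max valid r = %.4g mm)",
                   sqrt(max(r2[arg <= 0])),
                   abs(s$radius) / sqrt(max(1 + s$conic, 1e-300))))
    z <- c0 * r2 / (1 + sqrt(arg))
  } else {
    z <- 0 * r2
  }
  z + s$a4 * r2^2 + s$a6 * r2^3
}

# d(sag)/dr, used for surface normals
sag_slope <- function(surface, r) {
  s <- surface
  sl <- 0 * r
  if (is.finite(s$radius)) {
    c0 <- 1 / s$radius
    arg <- pmax(1 - (1 + s$conic) * c0^2 * r^2, 1e-300)
    sl <- c0 * r / sqrt(arg)
  }
  sl + 4 * s$a4 * r^3 + 6 * s$a6 * r^5
}

#' Thick lens element with pose
#'
#' Two conic/aspheric surfaces separated by a centre thickness, with a
#' misalignment pose: transverse decentration along y and rotation (tilt)
#' about the y axis through the lens centre. The pose envelope (|decenter|
#' <= 2000 um, |tilt| <= 15 deg) is the validity range of the thin-element
#' projection used by the field engine.
#'
#' @param front,back `conic_surface` objects (sag measured toward +z from
#'   each vertex).
#' @param center_thickness axial thickness between vertices in mm.
#' @param material_index refractive index of the lens material.
#' @param decenter_y transverse shift along y in micrometres.
#' @param tilt_y rotation about the y axis in degrees.
#' @param axial_position z of the lens centre (mid-thickness) in mm.
#' @return an object of class `lens_element`.
#' @export
lens_element <- function(front, back, center_thickness, material_index,
                         decenter_y = 0, tilt_y = 0, axial_position = 0) {
  stopifnot(inherits(front, "conic_surface"), inherits(back, "conic_surface"))
  if (center_thickness <= 0) stop("center_thickness must be positive")
  if (material_index < 1) stop("material_index must be >= 1")
  check_pose(decenter_y, tilt_y)
  structure(list(front = front, back = back,
                 center_thickness = center_thickness,
                 material_index = material_index,
                 decenter_y = decenter_y, tilt_y = tilt_y,
                 axial_position = axial_position),
            class = "lens_element")
}

check_pose <- function(decenter_y, tilt_y) {
  if (abs(decenter_y) > 2000)
    stop("decenter_y outside the +/-2000 um validity envelope")
  if (abs(tilt_y) > 15)
    stop("tilt_y outside the +/-15 degree validity envelope")
  invisible(TRUE)
}

#' @export
print.lens_element <- function(x, ...) {
  cat(sprintf(
    "<lens_element> t %.3g mm, n %.4f, z %.4g mm, decenter %g um, tilt %g deg\n",
    x$center_thickness, x$material_index, x$axial_position,
    x$decenter_y, x$tilt_y))
  cat("  front: "); print(x$front)
  cat("  back:  "); print(x$back)
  invisible(x)
}

#' Paraxial power of a lens element
#'
#' Thick-lens (Gullstrand) combination of the two surface powers with the
#' reduced centre thickness.
#'
#' @param element a `lens_element`.
#' @param n_before,n_after refractive indices of the surrounding media.
#' @return power in diopters.
#' @export
paraxial_power <- function(element, n_before, n_after = n_before) {
  nl <- element$material_index
  c1 <- if (is.finite(element$front$radius)) 1 / element$front$radius else 0
  c2 <- if (is.finite(element$back$radius)) 1 / element$back$radius else 0
  P1 <- (nl - n_before) * c1       # 1/mm
  P2 <- (n_after - nl) * c2
  P <- P1 + P2 - P1 * P2 * element$center_thickness / nl
  P * 1000                         # diopters
}

#' Thin-element OPD map of a posed lens
#'
#' Projects the lens onto a single phase screen at its centre plane: for
#' each transverse grid sample the optical path is integrated along the
#' straight line parallel to z through the decentered/tilted lens volume
#' (chord length inside the glass, surrounding medium elsewhere), relative
#' to the axial reference. Valid for the small numerical apertures and
#' small tilts of this bench; samples outside the (posed) clear aperture
#' are marked opaque (`NA`).
#'
#' @param element a `lens_element`.
#' @param n_grid samples per axis.
#' @param pitch grid pitch in mm.
#' @param n_before,n_after surrounding refractive indices.
#' @return an `opd_map` (um), `NA` outside the clear aperture.
#' @export
element_opd_map <- function(element, n_grid, pitch, n_before,
                            n_after = n_before) {
  check_pose(element$decenter_y, element$tilt_y)
  el <- element
  th <- el$tilt_y * pi / 180
  dy <- el$decenter_y * 1e-3       # um -> mm
  ax <- ((0:(n_grid - 1L)) - n_grid %/% 2L) * pitch
  t2 <- el$center_thickness / 2
  # straight bench line through (x0, y0): in the lens frame it runs
  # x_l(z_l) = x0/cos(th) - z_l*tan(th), y_l = y0 - dy  (rotation about y)
  X <- matrix(ax / cos(th), n_grid, n_grid)
  Yl <- matrix(ax - dy, n_grid, n_grid, byrow = TRUE)
  # entry/exit z_l by fixed-point iteration on z = -t/2 + sag_f (resp.
  # z = +t/2 - sag_b'); sag slopes are tiny so 4 iterations converge to
  # well below a nanometre
  zf <- matrix(-t2, n_grid, n_grid)
  zb <- matrix(+t2, n_grid, n_grid)
  for (i in 1:4) {
    zf <- -t2 + sag_clamped(el$front, X - zf * tan(th), Yl)
    zb <- +t2 + sag_back_clamped(el$back, X - zb * tan(th), Yl)
  }
  chord <- pmax(zb - zf, 0) / cos(th)
  opd_mm <- (el$material_index - n_before) * chord  # n_after == n_before here
  if (abs(n_after - n_before) > 1e-12)
    warning("asymmetric surrounding media treated with the entrance index")
  ctr <- n_grid %/% 2L + 1L
  # aperture in the lens frame (evaluate at the mid-plane crossing)
  rl2 <- (X)^2 + Yl^2
  semi <- min(el$front$semi_aperture, el$back$semi_aperture)
  opd_um <- (opd_mm - opd_mm[ctr, ctr]) * 1e3
  opd_um[rl2 > semi^2] <- NA_real_
  opd_map(opd_um, pitch, 2 * semi)
}

# sag evaluated with out-of-domain radii clamped (those samples are masked
# by the aperture afterwards)
sag_clamped <- function(surface, x, y) {
  r2 <- x^2 + y^2
  if (is.finite(surface$radius) && surface$conic > -1) {
    r2max <- (surface$radius^2 / (1 + surface$conic)) * (1 - 1e-9)
    r2 <- pmin(r2, r2max)
  }
  s <- surface
  z <- 0 * r2
  if (is.finite(s$radius)) {
    c0 <- 1 / s$radius
    arg <- pmax(1 - (1 + s$conic) * c0^2 * r2, 0)
    z <- c0 * r2 / (1 + sqrt(arg))
  }
  z + s$a4 * r2^2 + s$a6 * r2^3
}

sag_back_clamped <- function(surface, x, y) sag_clamped(surface, x, y)

# Phase screen of one posed lens surface, evaluated at the surface's
# *unposed* vertex plane: for each bench grid sample the z-offset from the
# vertex plane to the decentered/tilted surface along the z-parallel line
# is computed (fixed-point iteration, as in element_opd_map), and the OPD
# is (n1 - n2) * offset. Splitting a lens into its two surface screens
# with a true propagation through the glass preserves the thick-lens
# principal planes, which matters when the incident beam is strongly
# converging (as it is at this bench's IOL).
posed_surface_screen <- function(element, which = c("front", "back"),
                                 n_grid, pitch, n1, n2) {
  which <- match.arg(which)
  th <- element$tilt_y * pi / 180
  dy <- element$decenter_y * 1e-3
  v <- if (which == "front") -element$center_thickness / 2 else
    +element$center_thickness / 2
  surf <- element[[which]]
  ax <- ((0:(n_grid - 1L)) - n_grid %/% 2L) * pitch
  X <- matrix(ax / cos(th), n_grid, n_grid)
  Xb <- matrix(ax, n_grid, n_grid)
  Yl <- matrix(ax - dy, n_grid, n_grid, byrow = TRUE)
  zl <- matrix(v, n_grid, n_grid)
  for (i in 1:4) zl <- v + sag_clamped(surf, X - zl * tan(th), Yl)
  z_rel <- (zl - Xb * sin(th)) / cos(th) - v
  opd_um <- (n1 - n2) * z_rel * 1e3
  ctr <- n_grid %/% 2L + 1L
  opd_um <- opd_um - opd_um[ctr, ctr]
  rl2 <- (X - zl * tan(th))^2 + Yl^2
  opd_um[rl2 > surf$semi_aperture^2] <- NA_real_
  opd_map(opd_um, pitch, 2 * surf$semi_aperture)
}

#' Exact vector refraction of a ray at a surface
#'
#' Snell's law in vector form at the local surface normal. The ray is
#' advanced to its intersection with the surface (Newton iteration along
#' the ray) and its accumulated optical path length is increased by
#' `n1 * geometric path`. Rays that miss the clear aperture are flagged
#' dead (`escaped`), total internal reflection terminates the ray (`tir`).
#'
#' @param ray a `ray` (see [make_ray()]).
#' @param surface a `conic_surface`.
#' @param vertex_z axial position of the surface vertex in mm.
#' @param n1,n2 refractive indices before/after the surface.
#' @return the refracted `ray`.
#' @export
refract_ray <- function(ray, surface, vertex_z, n1, n2) {
  if (!ray$alive) return(ray)
  p <- ray$position; d <- ray$direction
  # Newton iteration for t with F(t) = p_z + t d_z - vertex_z - sag(x, y)
  t <- (vertex_z - p[3]) / d[3]
  for (i in 1:12) {
    q <- p + t * d
    r <- sqrt(q[1]^2 + q[2]^2)
    if (r > surface$semi_aperture * 1.5) break
    Fv <- q[3] - vertex_z - sag_clamped(surface, q[1], q[2])
    sl <- sag_slope(surface, max(r, 1e-12))
    dF <- d[3] - sl * (q[1] * d[1] + q[2] * d[2]) / max(r, 1e-12)
    step <- Fv / dF
    t <- t - step
    if (abs(step) < 1e-13) break
  }
  q <- p + t * d
  r <- sqrt(q[1]^2 + q[2]^2)
  if (t < 0 || r > surface$semi_aperture) {
    ray$alive <- FALSE; ray$fate <- "escaped"
    return(ray)
  }
  sl <- sag_slope(surface, max(r, 1e-12))
  nrm <- c(-sl * q[1] / max(r, 1e-12), -sl * q[2] / max(r, 1e-12), 1)
  nrm <- nrm / sqrt(sum(nrm^2))
  ci <- -sum(d * nrm)
  if (ci < 0) { nrm <- -nrm; ci <- -ci }
  eta <- n1 / n2
  s2 <- eta^2 * (1 - ci^2)
  if (s2 > 1) {
    ray$alive <- FALSE; ray$fate <- "tir"
    return(ray)
  }
  ct <- sqrt(1 - s2)
  ray$direction <- eta * d + (eta * ci - ct) * nrm
  ray$direction <- ray$direction / sqrt(sum(ray$direction^2))
  ray$position <- q
  ray$opl <- ray$opl + n1 * t
  ray
}

#' Construct a geometric ray
#'
#' @param position numeric length-3 (mm).
#' @param direction numeric length-3 direction cosines (normalized).
#' @param opl accumulated optical path length (mm).
#' @return an object of class `ray`.
#' @export
make_ray <- function(position, direction = c(0, 0, 1), opl = 0) {
  direction <- direction / sqrt(sum(direction^2))
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 opl = opl, alive = TRUE, fate = "ok"),
            class = "ray")
}
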
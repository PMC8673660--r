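# Geometric ray-tracing engine: exact sequential refraction through the
# bench surfaces, exit-pupil OPD against a reference sphere, and the
# pupil-function (FFT) PSF -- the classic ray-based comparator for the
# field-traced results.

#' Bundle of geometric rays
#'
#' Rays are stored column-wise in plain vectors for vectorized tracing.
#' `px`, `py` are the normalized launch (pupil) coordinates in the unit
#' disk.
#'
#' @param x,y,z positions (mm).
#' @param dx,dy,dz direction cosines.
#' @param px,py normalized pupil coordinates.
#' @return an object of class `ray_bundle`.
#' @export
ray_bundle <- function(x, y, z, dx, dy, dz, px, py) {
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(abs(nrm - 1) > 1e-9)) { dx <- dx/nrm; dy <- dy/nrm; dz <- dz/nrm }
  if (any(px^2 + py^2 > 1 + 1e-9))
    stop("pupil coordinates must lie in the unit disk")
  structure(list(x = x, y = y, z = z, dx = dx, dy = dy, dz = dz,
                 opl = numeric(length(x)), alive = rep(TRUE, length(x)),
                 px = px, py = py),
            class = "ray_bundle")
}

#' @export
print.ray_bundle <- function(x, ...) {
  cat(sprintf("<ray_bundle> %d rays, %d alive, z = %.4g mm\n",
              length(x$x), sum(x$alive), x$z[1]))
  invisible(x)
}

#' Hexapolar pupil sampling
#'
#' Centre ray plus `n_rings` concentric rings with 6k points on ring k --
#' the standard quasi-uniform pupil pattern for aberration analysis.
#'
#' @param n_rings number of rings (>= 4 for meaningful fits).
#' @return data.frame with normalized pupil coordinates `px`, `py`.
#' @export
hexapolar_pupil <- function(n_rings = 16) {
  if (n_rings < 1) stop("n_rings must be >= 1")
  px <- 0; py <- 0
  for (k in seq_len(n_rings)) {
    m <- 6L * k
    a <- 2 * pi * (0:(m - 1L)) / m
    px <- c(px, (k / n_rings) * cos(a))
    py <- c(py, (k / n_rings) * sin(a))
  }
  data.frame(px = px, py = py)
}

# regular grid pupil sampling (one ray per OPD raster sample)
grid_pupil <- function(n_grid) {
  u <- ((0:(n_grid - 1L)) - n_grid %/% 2L) / (n_grid / 2)
  g <- expand.grid(px = u, py = u)
  g[g$px^2 + g$py^2 <= 1, ]
}

# --- vectorized surface interactions -----------------------------------

# advance all rays to the plane z = z0 (no refraction)
bundle_to_plane <- function(b, z0, n) {
  t <- (z0 - b$z) / b$dz
  b$x <- b$x + t * b$dx; b$y <- b$y + t * b$dy; b$z <- b$z + t * b$dz
  b$opl <- b$opl + n * t
  b
}

# intersect + refract at a conic/aspheric surface with vertex at vertex_z
bundle_refract <- function(b, surface, vertex_z, n1, n2) {
  al <- b$alive
  t <- (vertex_z - b$z) / b$dz
  for (i in 1:12) {
    qx <- b$x + t * b$dx; qy <- b$y + t * b$dy; qz <- b$z + t * b$dz
    r <- sqrt(qx^2 + qy^2)
    Fv <- qz - vertex_z - sag_clamped(surface, qx, qy)
    sl <- sag_slope(surface, pmax(r, 1e-12))
    dF <- b$dz - sl * (qx * b$dx + qy * b$dy) / pmax(r, 1e-12)
    step <- Fv / dF
    t <- t - step
    if (max(abs(step[al])) < 1e-13) break
  }
  qx <- b$x + t * b$dx; qy <- b$y + t * b$dy; qz <- b$z + t * b$dz
  r <- sqrt(qx^2 + qy^2)
  dead <- al & (r > surface$semi_aperture | t < -1e-9)
  sl <- sag_slope(surface, pmax(r, 1e-12))
  nx <- -sl * qx / pmax(r, 1e-12); ny <- -sl * qy / pmax(r, 1e-12); nz <- 1
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx/nn; ny <- ny/nn; nz <- nz/nn
  ci <- -(b$dx * nx + b$dy * ny + b$dz * nz)
  fl <- ci < 0
  nx[fl] <- -nx[fl]; ny[fl] <- -ny[fl]; nz[fl] <- -nz[fl]; ci[fl] <- -ci[fl]
  eta <- n1 / n2
  s2 <- eta^2 * (1 - ci^2)
  tir <- al & s2 > 1
  ct <- sqrt(pmax(1 - s2, 0))
  g <- eta * ci - ct
  b$x <- qx; b$y <- qy; b$z <- qz
  b$opl <- b$opl + n1 * t
  b$dx <- eta * b$dx + g * nx
  b$dy <- eta * b$dy + g * ny
  b$dz <- eta * b$dz + g * nz
  nrm <- sqrt(b$dx^2 + b$dy^2 + b$dz^2)
  b$dx <- b$dx/nrm; b$dy <- b$dy/nrm; b$dz <- b$dz/nrm
  b$alive <- al & !dead & !tir
  b
}

# rotate bundle about the y axis by angle th (radians), about point c
rotate_bundle_y <- function(b, th, cz) {
  cs <- cos(th); sn <- sin(th)
  x <- b$x; z <- b$z - cz
  b$x <- cs * x + sn * z
  b$z <- -sn * x + cs * z + cz
  dx <- b$dx; dz <- b$dz
  b$dx <- cs * dx + sn * dz
  b$dz <- -sn * dx + cs * dz
  b
}

# refract through a posed lens element (transform into the lens frame,
# trace both surfaces, transform back)
bundle_through_element <- function(b, el, n_before, n_after = n_before) {
  th <- el$tilt_y * pi / 180
  dy <- el$decenter_y * 1e-3
  cz <- el$axial_position
  b$y <- b$y - dy
  if (th != 0) b <- rotate_bundle_y(b, -th, cz)
  t2 <- el$center_thickness / 2
  b <- bundle_refract(b, el$front, cz - t2, n_before, el$material_index)
  b <- bundle_refract(b, el$back, cz + t2, el$material_index, n_after)
  if (th != 0) b <- rotate_bundle_y(b, th, cz)
  b$y <- b$y + dy
  b
}

# ideal aberration-free thin lens of power P (1/mm), stigmatic for the
# bench's conjugates: the screen converts a perfect sphere converging at
# R_in behind the plane into a perfect sphere converging at R_out, with
# 1/R_out = 1/R_in + P/n. Its OPD is the exact sphere-to-sphere phase
# (a parabolic screen would itself carry spherical aberration at these
# steep conjugates); rays are bent by the screen's transverse gradient.
bundle_ideal_lens <- function(b, P, plane_z, n_medium, R_in) {
  b <- bundle_to_plane(b, plane_z, n_medium)
  n <- n_medium
  r2 <- b$x^2 + b$y^2
  if (is.finite(R_in)) {
    R_out <- n * R_in / (n + P * R_in)
    s_in <- sqrt(r2 + R_in^2)
    opd_in <- n * (s_in - R_in); gin <- 1 / s_in
  } else {
    R_out <- n / P
    opd_in <- 0; gin <- 0
  }
  s_out <- sqrt(r2 + R_out^2)
  opd <- opd_in - n * (s_out - R_out)
  gx <- n * b$x * (gin - 1 / s_out)
  gy <- n * b$y * (gin - 1 / s_out)
  ux <- n * b$dx + gx
  uy <- n * b$dy + gy
  b$dx <- ux / n; b$dy <- uy / n
  b$dz <- sqrt(pmax(1 - b$dx^2 - b$dy^2, 0))
  b$opl <- b$opl + opd
  b
}

# trace a bundle through an ordered list of surface events
bundle_through_train <- function(b, events) {
  for (ev in events) {
    b <- switch(ev$type,
      conic = bundle_refract(b, ev$surface, ev$z, ev$n1, ev$n2),
      element = bundle_through_element(b, ev$element, ev$n1, ev$n2),
      ideal = bundle_ideal_lens(b, ev$P, ev$z, ev$n1, ev$R_in))
  }
  b
}

# --- bench-level tracing ------------------------------------------------

#' Trace a collimated bundle through a model-eye bench
#'
#' Launches a bundle filling the aperture stop (collimated, parallel to the
#' axis -- the object is at optical infinity) and traces it with exact
#' refraction through cornea, wet-cell windows and the posed IOL into image
#' space. The bundle is *not* advanced to the screen, so the caller can
#' choose a reference sphere.
#'
#' @param bench a `model_eye_bench` (see [build_bench()]).
#' @param n_rings hexapolar ring count; alternatively supply `pupil`.
#' @param pupil optional data.frame of normalized pupil coordinates.
#' @param field_angle incoming beam angle in the x-z plane (radians).
#' @return a traced `ray_bundle` in image space.
#' @export
trace_bundle <- function(bench, n_rings = 16, pupil = NULL, field_angle = 0) {
  if (is.null(pupil)) pupil <- hexapolar_pupil(n_rings)
  R <- bench$stop$diameter / 2
  n <- nrow(pupil)
  b <- ray_bundle(x = pupil$px * R, y = pupil$py * R,
                  z = rep(bench$stop$z, n),
                  dx = rep(sin(field_angle), n), dy = rep(0, n),
                  dz = rep(cos(field_angle), n),
                  px = pupil$px, py = pupil$py)
  b <- bundle_through_train(b, bench_surface_train(bench))
  if (!any(b$alive)) stop("all rays dead: bench geometry is inconsistent")
  b
}

#' Exit-pupil OPD map from a traced bundle
#'
#' Optical path differences on a reference sphere centred at `center`
#' (default: the axial point of the fixed screen), relative to the chief
#' (central) ray; piston removed. With a regular-grid bundle the map is a
#' raster over the pupil; with a scattered bundle the samples are gridded
#' by a Zernike reconstruction (radial order 10).
#'
#' For each image-space ray the OPL projected to the reference point C is
#' `opl + n * (d . (C - p))`, which is constant for a perfect spherical
#' wave converging on C; its negative deviation from the chief ray is the
#' wavefront error (positive W = wavefront advanced, marginal focus short).
#'
#' @param bundle traced `ray_bundle` in image space.
#' @param center reference sphere centre (x, y, z) in mm.
#' @param n_image image-space refractive index.
#' @param pupil_diameter physical pupil zone diameter (mm) recorded in the
#'   map (for Zernike scaling).
#' @param n_grid raster size when gridding is needed.
#' @param pupil_plane_z when given, the map is indexed by the rays'
#'   transverse positions on this exit-pupil plane (normalized to
#'   `pupil_diameter`) instead of their launch coordinates, and gridded by
#'   a Zernike reconstruction.
#' @return an `opd_map` in micrometres; attribute `samples` holds the
#'   per-ray values.
#' @export
exit_pupil_opd <- function(bundle, center, n_image, pupil_diameter,
                           n_grid = 64, pupil_plane_z = NULL) {
  al <- bundle$alive
  if (mean(al) < 0.9)
    stop(sprintf("only %.0f%% of rays alive; need >= 90%%", 100 * mean(al)))
  proj <- bundle$opl + n_image *
    ((center[1] - bundle$x) * bundle$dx +
     (center[2] - bundle$y) * bundle$dy +
     (center[3] - bundle$z) * bundle$dz)
  chief <- which.min(bundle$px^2 + bundle$py^2)
  W <- -(proj - proj[chief]) * 1e3   # um; sign: positive = advanced
  W[!al] <- NA
  if (!is.null(pupil_plane_z)) {
    tt <- (pupil_plane_z - bundle$z) / bundle$dz
    ex <- (bundle$x + tt * bundle$dx) / (pupil_diameter / 2)
    ey <- (bundle$y + tt * bundle$dy) / (pupil_diameter / 2)
    samples <- data.frame(px = ex, py = ey, opd = W)
    keep <- al & ex^2 + ey^2 <= 1.05^2   # tolerate pupil distortion
    zf <- zernike_lsq(ex[keep], ey[keep], W[keep], max_order = 12)
    u <- ((0:(n_grid - 1L)) - n_grid %/% 2L) / (n_grid / 2)
    g <- expand.grid(px = u, py = u)
    m <- matrix(zernike_eval(zf, g$px, g$py), n_grid, n_grid)
    m[matrix(g$px^2 + g$py^2 > 1, n_grid, n_grid)] <- NA
    om <- opd_map(m, pitch = pupil_diameter / n_grid,
                  aperture_diameter = pupil_diameter)
    attr(om, "samples") <- samples
    attr(om, "zernike") <- zf
    return(om)
  }
  samples <- data.frame(px = bundle$px, py = bundle$py, opd = W)

  on_grid <- is_grid_pupil(bundle$px, bundle$py, n_grid)
  if (!is.null(on_grid)) {
    m <- matrix(NA_real_, n_grid, n_grid)
    m[cbind(on_grid$i, on_grid$j)] <- W
    om <- opd_map(m, pitch = pupil_diameter / n_grid,
                  aperture_diameter = pupil_diameter)
  } else {
    zf <- zernike_lsq(bundle$px[al], bundle$py[al], W[al], max_order = 10)
    u <- ((0:(n_grid - 1L)) - n_grid %/% 2L) / (n_grid / 2)
    g <- expand.grid(px = u, py = u)
    vals <- zernike_eval(zf, g$px, g$py)
    m <- matrix(vals, n_grid, n_grid)
    m[matrix(g$px^2 + g$py^2 > 1, n_grid, n_grid)] <- NA
    om <- opd_map(m, pitch = pupil_diameter / n_grid,
                  aperture_diameter = pupil_diameter)
  }
  attr(om, "samples") <- samples
  om
}

# detect whether pupil coordinates came from grid_pupil(n_grid); returns
# the raster indices or NULL
is_grid_pupil <- function(px, py, n_grid) {
  u <- ((0:(n_grid - 1L)) - n_grid %/% 2L) / (n_grid / 2)
  i <- match(round(px, 12), round(u, 12))
  j <- match(round(py, 12), round(u, 12))
  if (anyNA(i) || anyNA(j)) return(NULL)
  list(i = i, j = j)
}

#' Point spread function from an exit-pupil OPD map
#'
#' The classic FFT pupil-function PSF: `|FT(P * exp(i*2*pi*W/lambda))|^2`,
#' normalized so that the aberration-free PSF of the same pupil peaks at 1
#' (i.e. the raster values are Strehl-referenced intensities).
#'
#' @param opd an `opd_map` raster over the pupil (`NA` outside).
#' @param wavelength vacuum wavelength in nm.
#' @param image_distance reference sphere radius (pupil to image) in mm.
#' @param n_image image-space index.
#' @param output_pitch image-plane sample pitch in mm.
#' @param n_out output raster size.
#' @return list with `psf` (matrix, peak-normalized to the diffraction
#'   limit), `pitch` (mm), and `strehl` (max of psf).
#' @export
psf_from_pupil <- function(opd, wavelength, image_distance, n_image = 1,
                           output_pitch, n_out = 256) {
  W <- opd$opd
  P <- !is.na(W)
  lam0 <- wavelength * 1e-6
  # W follows the clinical OPD-excess convention (positive corneal SA);
  # the transmitted-phase screen is its negative
  U <- matrix(0i, nrow(W), ncol(W))
  U[P] <- exp(-2i * pi * (W[P] * 1e-3) / lam0)
  alpha <- n_image * opd$pitch * output_pitch / (lam0 * image_distance)
  I <- Mod(czt2(U, alpha, n_out))^2
  I0 <- Mod(czt2((P + 0) + 0i, alpha, n_out))^2
  psf <- I / max(I0)
  list(psf = psf, pitch = output_pitch, strehl = max(psf))
}

#' Geometric-optics image simulation
#'
#' Incoherent imaging model used by the ray-tracing comparator: the target
#' is scaled by the paraxial magnification onto the image grid and convolved
#' with the ray-traced PSF (isoplanatic approximation). No interference
#' fringes can appear: intensities, not fields, are superposed.
#'
#' @param bench a focused `model_eye_bench`.
#' @param target a `transmission_mask`.
#' @param output_pitch image raster pitch (mm); match the field-traced image.
#' @param n_out image raster size.
#' @param n_grid pupil raster size for the PSF.
#' @return list with `image` (intensity raster), `pitch`, and the `psf` used.
#' @export
ray_image_simulation <- function(bench, target, output_pitch, n_out = 512,
                                 n_grid = 64) {
  m <- bench_magnification(bench)
  ideal <- resample_mask(target, output_pitch / abs(m), n_out, invert = m < 0)
  pr <- ray_psf(bench, output_pitch = output_pitch, n_out = n_out,
                n_grid = n_grid)
  # incoherent convolution; the PSF is wrapped so its centre sample sits at
  # the array origin
  kern <- stats::fft(fft_shift2(pr$psf))
  img <- Re(stats::fft(stats::fft(ideal) * kern, inverse = TRUE)) /
    length(ideal) * output_pitch^2
  img <- pmax(img, 0)
  list(image = img / max(img), pitch = output_pitch, psf = pr)
}
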
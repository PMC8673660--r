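# Image-quality metrics: Zernike wavefront decomposition (OSA/ANSI
# convention, coefficients in micrometres), Strehl ratio, MTF by Fourier
# transform of the PSF, and the coherent field-traced PSF/image of the
# bench.

zernike_modes <- function(max_order) {
  out <- NULL
  for (n in 0:max_order)
    for (m in seq(-n, n, by = 2))
      out <- rbind(out, c(j = (n * (n + 2) + m) / 2, n = n, m = m))
  as.data.frame(out)
}

# OSA/ANSI-normalized Zernike polynomial Z_n^m on the unit disk
zernike_poly <- function(n, m, px, py) {
  rho <- sqrt(px^2 + py^2)
  th <- atan2(py, px)
  am <- abs(m)
  R <- 0
  for (k in 0:((n - am) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) *
         factorial((n - am) / 2 - k)) * rho^(n - 2 * k)
  }
  N <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  if (m >= 0) N * R * cos(am * th) else N * R * sin(am * th)
}

# least-squares Zernike coefficients from scattered samples
zernike_lsq <- function(px, py, w, max_order = 8) {
  modes <- zernike_modes(max_order)
  X <- vapply(seq_len(nrow(modes)),
              function(i) zernike_poly(modes$n[i], modes$m[i], px, py),
              numeric(length(px)))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X))
    stop("rank-deficient pupil sampling; reduce max_order or add samples")
  modes$coefficient <- qr.coef(qr_, w)
  class(modes) <- c("zernike_fit", "data.frame")
  modes
}

zernike_eval <- function(fit, px, py) {
  v <- 0
  for (i in seq_len(nrow(fit)))
    v <- v + fit$coefficient[i] * zernike_poly(fit$n[i], fit$m[i], px, py)
  v
}

#' Zernike decomposition of an OPD map
#'
#' Least-squares fit of OSA/ANSI-normalized Zernike polynomials over the
#' unit disk scaled to `aperture_diameter`. Coefficients are reported in
#' micrometres; the primary spherical aberration Z(4,0) is the coefficient
#' of `sqrt(5)*(6*rho^4 - 6*rho^2 + 1)`.
#'
#' @param opd an `opd_map` (um).
#' @param aperture_diameter fit zone diameter in mm (default: the map's
#'   declared zone; may be smaller to fit a sub-aperture).
#' @param max_order maximum radial order.
#' @return a `zernike_fit` data.frame with columns `j`, `n`, `m`,
#'   `coefficient` (um).
#' @export
zernike_fit <- function(opd, aperture_diameter = opd$aperture_diameter,
                        max_order = 8) {
  stopifnot(inherits(opd, "opd_map"))
  ng1 <- nrow(opd$opd); ng2 <- ncol(opd$opd)
  ax1 <- ((0:(ng1 - 1L)) - ng1 %/% 2L) * opd$pitch
  ax2 <- ((0:(ng2 - 1L)) - ng2 %/% 2L) * opd$pitch
  R <- aperture_diameter / 2
  PX <- matrix(ax1 / R, ng1, ng2)
  PY <- matrix(ax2 / R, ng1, ng2, byrow = TRUE)
  inside <- PX^2 + PY^2 <= 1
  ok <- inside & !is.na(opd$opd)
  if (sum(ok) < 0.95 * sum(inside))
    stop("OPD defined over < 95% of the requested aperture")
  zernike_lsq(PX[ok], PY[ok], opd$opd[ok], max_order)
}

#' Read one coefficient from a Zernike fit
#' @param fit a `zernike_fit`.
#' @param n,m radial and azimuthal order.
#' @return coefficient in um.
#' @export
zernike_coef <- function(fit, n, m) {
  i <- which(fit$n == n & fit$m == m)
  if (!length(i)) stop("mode not in fit")
  fit$coefficient[i]
}

#' @export
print.zernike_fit <- function(x, ...) {
  cat("<zernike_fit> OSA/ANSI coefficients (um):\n")
  top <- x[order(-abs(x$coefficient)), ][seq_len(min(8, nrow(x))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  Z(%d,%+d) = %+.4f\n", top$n[i], top$m[i],
                top$coefficient[i]))
  invisible(x)
}

#' Strehl ratio of a PSF against a reference
#'
#' Ratio of peak intensities. The reference must be computed with the same
#' input power, pupil and sample pitch (the package convention: the same
#' bench with ideal phase elements of identical paraxial powers).
#'
#' @param psf,reference PSF objects as returned by [compute_field_psf()]
#'   (lists with `intensity` and `pitch`) or plain matrices on a common
#'   pitch.
#' @return Strehl ratio in (0, 1.02].
#' @export
strehl <- function(psf, reference) {
  geti <- function(p) if (is.list(p)) p$intensity else p
  getp <- function(p) if (is.list(p)) p$pitch else NA_real_
  p1 <- getp(psf); p2 <- getp(reference)
  if (!is.na(p1) && !is.na(p2) && abs(p1 - p2) > 1e-12 * p2)
    stop("psf and reference pitches differ")
  s <- max(geti(psf)) / max(geti(reference))
  if (s > 1.02) warning(sprintf("Strehl %.4f > 1.02: check normalization", s))
  s
}

#' MTF from a PSF raster
#'
#' Modulus of the 2-D Fourier transform of the PSF intensity, normalized to
#' 1 at zero frequency; the x and y cross-sections (tangential/sagittal
#' analogue for this bench's misalignment axes) are returned against
#' spatial frequency in cycles/mm at the image plane.
#'
#' @param psf PSF object (list with `intensity`, `pitch`) or matrix.
#' @param pitch sample pitch in mm when `psf` is a matrix.
#' @return list with `freq` (cycles/mm), `mtf_x`, `mtf_y`, and the full
#'   2-D `mtf` matrix.
#' @export
mtf_from_psf <- function(psf, pitch = NULL) {
  I <- if (is.list(psf)) psf$intensity else psf
  if (is.list(psf)) pitch <- psf$pitch
  if (is.null(pitch)) stop("pitch required")
  M <- Mod(fft2_centered(I))
  n1 <- nrow(I); n2 <- ncol(I)
  c1 <- n1 %/% 2L + 1L; c2 <- n2 %/% 2L + 1L
  M <- M / M[c1, c2]
  freq <- (0:(n1 - c1)) / (n1 * pitch)
  list(freq = freq,
       mtf_x = M[c1:n1, c2],
       mtf_y = M[c1, c2:n2],
       mtf = M, pitch_freq = 1 / (n1 * pitch))
}

#' Field-traced PSF of the bench
#'
#' Propagates a plane wave (object mask removed) through stop, cornea, wet
#' cell and posed IOL to the fixed screen with the angular-spectrum /
#' scaled-Fresnel engine, and returns the screen intensity. The output
#' window is centred on the geometric image point predicted by a quick ray
#' trace so that laterally displaced PSFs stay in frame.
#'
#' @param bench a focused `model_eye_bench`.
#' @param samples field grid samples (default from the bench config).
#' @param output_pitch screen sample pitch in mm (default chosen so the
#'   diffraction-limited core spans >= 16 samples).
#' @param n_out output raster size.
#' @param ideal logical: replace cornea and IOL by ideal phase elements of
#'   identical paraxial power (the Strehl reference bench).
#' @param center optional output window centre (mm); default ray-predicted.
#' @return list with `intensity`, `pitch`, `center`, `field`.
#' @export
compute_field_psf <- function(bench, samples = bench$grid$n,
                              output_pitch = NULL, n_out = 512,
                              ideal = FALSE, center = NULL) {
  if (is.null(bench$screen_z))
    stop("bench is not focused; run find_focal_plane() first")
  core <- 1.22 * bench$wavelength * 1e-6 /
    (bench$pupil_diameter / bench_image_zeta(bench))
  if (is.null(output_pitch)) {
    output_pitch <- core / 8      # >= 16 samples across the Airy core
  } else if (output_pitch > core / 8 * (1 + 1e-9)) {
    stop(sprintf(
      "PSF undersampled: output_pitch %.3g um puts < 16 samples across the core; use <= %.3g um",
      output_pitch * 1e3, core / 8 * 1e3))
  }
  if (is.null(center)) {
    center <- if (ideal) c(0, 0) else ray_image_centroid(bench)
  }
  pw <- generate_plane_wave(samples, bench$grid$window,
                            wavelength = bench$wavelength)
  # the aberration-free reference is evaluated at its own focal plane:
  # its peak is the diffraction-limited normalization for the Strehl ratio
  z_out <- if (ideal) find_focal_plane(bench, samples = samples,
                                       ideal = TRUE) else bench$screen_z
  f <- field_through_bench(bench, pw, output_pitch = output_pitch,
                           n_out = n_out, center = center, ideal = ideal,
                           z_out = z_out)
  list(intensity = field_intensity(f), pitch = output_pitch,
       center = center, field = f)
}

#' Simulate the target image on the screen
#'
#' With `engine = "field"` the coherent field of the infinity-presented
#' USAF target (its plane-wave spectrum weighted by the mask) is propagated
#' through the bench to the screen: diffraction and interference are fully
#' retained, and the bar interiors show coherent fringing. With
#' `engine = "ray"` the geometric image is convolved with the ray-traced
#' PSF: no interference is possible.
#'
#' @param bench a focused `model_eye_bench`.
#' @param target a `transmission_mask`.
#' @param engine `"field"` or `"ray"`.
#' @param samples field grid samples.
#' @param n_out image raster size.
#' @param output_pitch image pitch in mm; default frames the geometric
#'   image with 20% margin.
#' @return list with `image` (intensity, peak-normalized), `pitch`,
#'   `magnification`.
#' @export
simulate_image <- function(bench, target, engine = c("field", "ray"),
                           samples = bench$grid$n, n_out = 512,
                           output_pitch = NULL) {
  engine <- match.arg(engine)
  if (is.null(bench$screen_z))
    stop("bench is not focused; run find_focal_plane() first")
  m <- bench_magnification(bench)
  if (is.null(output_pitch))
    output_pitch <- 1.2 * abs(m) * max(target$extent) / n_out
  if (engine == "ray") {
    r <- ray_image_simulation(bench, target, output_pitch, n_out = n_out)
    return(list(image = r$image, pitch = output_pitch, magnification = m))
  }
  # plane-wave spectrum of the infinity-presented target, sampled at the
  # stop plane: U(u) = FT[mask](u / (lambda * f_coll))
  lam0 <- bench$wavelength * 1e-6
  p_stop <- bench$grid$window / samples
  nmask <- nrow(target$transmission)
  bw_need <- max(target$extent) / 2 / (lam0 * bench$collimator_f)
  if (bw_need > 1 / (2 * p_stop))
    stop(sprintf(paste0(
      "stop-plane grid cannot hold the target spectrum (%.3g > %.3g ",
      "cycles/mm); enlarge `samples` or shrink the target"),
      bw_need, 1 / (2 * p_stop)))
  alpha <- target$pitch * p_stop / (lam0 * bench$collimator_f)
  U <- czt2(sqrt(target$transmission) + 0i, alpha, samples) * target$pitch^2
  f0 <- complex_field(U, p_stop, wavelength = bench$wavelength)
  f <- field_through_bench(bench, f0, output_pitch = output_pitch,
                           n_out = n_out, center = c(0, 0))
  img <- field_intensity(f)
  list(image = img / max(img), pitch = output_pitch, magnification = m)
}
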
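#' Transmission mask
#'
#' @param transmission matrix of transmittance values in `[0, 1]`
#'   (first index x, second y, axis at the centre sample).
#' @param pitch sample spacing in mm.
#' @return an object of class `transmission_mask`.
#' @export
transmission_mask <- function(transmission, pitch) {
  if (any(transmission < 0 | transmission > 1))
    stop("transmission values must lie in [0, 1]")
  structure(list(transmission = transmission, pitch = pitch,
                 extent = dim(transmission) * pitch),
            class = "transmission_mask")
}

#' @export
print.transmission_mask <- function(x, ...) {
  cat(sprintf("<transmission_mask> %d x %d samples, %.3g x %.3g mm, open fraction %.3g\n",
              nrow(x$transmission), ncol(x$transmission),
              x$extent[1], x$extent[2], mean(x$transmission)))
  invisible(x)
}

usaf_bar_width <- function(group, element) {
  1 / (2 * 2^(group + (element - 1) / 6))   # mm
}

#' Generate a USAF-1951 style resolution target
#'
#' Three-bar resolution chart: each element is a vertical and a horizontal
#' triplet of bars of width `w` and length `5w`, with the standard spatial
#' frequency `2^(g + (e-1)/6)` line pairs/mm for group `g`, element `e`.
#' Elements of a group are laid out in a 3 x 2 block, groups stacked
#' vertically (a simplified rendering of the commercial chart; serial
#' numbers and legends are not reproduced). Bars are transmissive (value 1)
#' on an opaque background by default, so the imaged bars are the bright
#' ("white") features.
#'
#' @param extent physical side length in mm (square target).
#' @param samples grid samples per axis.
#' @param groups integer vector of chart groups to render.
#' @param bars_transmissive logical; `FALSE` inverts the polarity.
#' @return a `transmission_mask` with binary values.
#' @export
generate_usaf_target <- function(extent = 5, samples = 1024, groups = 2:4,
                                 bars_transmissive = TRUE) {
  pitch <- extent / samples
  wmin <- usaf_bar_width(max(groups), 6)
  if (wmin < 2 * pitch)
    stop(sprintf(
      "finest bar (%.4g um, group %d element 6) needs < 2 samples; use >= %d samples",
      wmin * 1e3, max(groups), ceiling(2 * extent / wmin)))
  M <- matrix(0, samples, samples)
  ax <- ((0:(samples - 1L)) - samples %/% 2L) * pitch
  paint <- function(x0, x1, y0, y1) {
    i <- which(ax >= x0 - pitch / 2 & ax < x1 - pitch / 2)
    j <- which(ax >= y0 - pitch / 2 & ax < y1 - pitch / 2)
    if (length(i) && length(j)) M[i, j] <<- 1
    invisible(NULL)
  }
  draw_element <- function(g, e, x, y) {
    w <- usaf_bar_width(g, e)
    for (k in 0:2) paint(x + 2 * k * w, x + (2 * k + 1) * w, y, y + 5 * w)
    for (k in 0:2) paint(x + 6 * w, x + 11 * w,
                         y + 2 * k * w, y + (2 * k + 1) * w)
  }
  blocks <- lapply(groups, function(g) {
    w1 <- usaf_bar_width(g, 1)
    c(width = 24 * w1, height = 21 * w1)
  })
  gap <- 0.04 * extent
  total_h <- sum(vapply(blocks, `[[`, 0, "height")) +
    gap * (length(groups) - 1)
  if (total_h > extent || max(vapply(blocks, `[[`, 0, "width")) > extent)
    stop("requested groups do not fit in the target extent")
  y <- total_h / 2
  for (gi in seq_along(groups)) {
    g <- groups[gi]; w1 <- usaf_bar_width(g, 1)
    bw <- blocks[[gi]]["width"]; bh <- blocks[[gi]]["height"]
    y <- y - bh
    x0 <- -bw / 2
    for (e in 1:6) {
      row <- (e - 1) %/% 2; col <- (e - 1) %% 2
      draw_element(g, e, x0 + col * 12 * w1, y + (2 - row) * 7 * w1)
    }
    y <- y - gap
  }
  if (!bars_transmissive) M <- 1 - M
  transmission_mask(M, pitch)
}

#' Uniform plane-wave field
#'
#' Unit-amplitude, zero-phase coherent field, the bench's illumination when
#' the object mask is removed.
#'
#' @param samples grid samples per axis.
#' @param window physical window side in mm.
#' @param amplitude field amplitude.
#' @param wavelength vacuum wavelength in nm.
#' @param medium_index embedding refractive index.
#' @return a `complex_field`.
#' @export
generate_plane_wave <- function(samples, window, amplitude = 1,
                                wavelength = 543.5, medium_index = 1) {
  complex_field(matrix(amplitude + 0i, samples, samples),
                pitch = window / samples, wavelength = wavelength,
                medium_index = medium_index)
}

#' Apply a transmission mask to a field
#'
#' @param field a `complex_field` on the same grid as the mask.
#' @param mask a `transmission_mask`.
#' @return the masked field (amplitude transmittance = sqrt of intensity
#'   transmittance for the binary masks used here they coincide).
#' @export
apply_mask <- function(field, mask) {
  if (!identical(dim(field$amp), dim(mask$transmission)) ||
      abs(field$pitch - mask$pitch) > 1e-12)
    stop("mask grid is not congruent with the field grid")
  field$amp <- field$amp * sqrt(mask$transmission)
  field
}

# bilinearly sample a mask at magnification m onto an n_out raster of pitch
# p_out (image-plane intensity of the geometric image)
resample_mask <- function(mask, obj_pitch_per_img_sample, n_out,
                          invert = FALSE) {
  n <- nrow(mask$transmission)
  ax_idx <- function(v) (v / mask$pitch) + n %/% 2 + 1
  xo <- ((0:(n_out - 1L)) - n_out %/% 2L) * obj_pitch_per_img_sample
  if (invert) xo <- -xo
  fi <- ax_idx(xo)
  fi0 <- pmin(pmax(floor(fi), 1), n - 1); fw <- fi - fi0
  fw[fi < 1 | fi > n] <- 0
  out_ix <- function(M) {
    A <- M[fi0, , drop = FALSE] * (1 - fw) + M[fi0 + 1, , drop = FALSE] * fw
    A[fi < 1 | fi > n, ] <- 0
    A
  }
  Mx <- out_ix(mask$transmission)
  My <- t(out_ix(t(Mx)))
  My
}
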
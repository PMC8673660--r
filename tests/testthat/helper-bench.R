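# Shared fixtures: the calibrated default bench and Strehl references are
# expensive, so they are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached_bench <- function() {
  if (is.null(.cache$bench)) {
    b <- build_bench()
    .cache$bench <- focus_bench(b, samples = 512)
  }
  .cache$bench
}

cached_ref_psf <- function(samples = 512) {
  key <- paste0("ref", samples)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- compute_field_psf(cached_bench(), samples = samples,
                                       ideal = TRUE)
  .cache[[key]]
}

pose_strehl <- function(decenter = 0, tilt = 0, samples = 512) {
  bench <- cached_bench()
  psf <- compute_field_psf(set_misalignment(bench, decenter, tilt),
                           samples = samples)
  strehl(psf, cached_ref_psf(samples))
}

# intensity-weighted centroid of a raster, in mm relative to the window
# centre
raster_centroid <- function(I, pitch) {
  n1 <- nrow(I); n2 <- ncol(I)
  x <- ((0:(n1 - 1)) - n1 %/% 2) * pitch
  y <- ((0:(n2 - 1)) - n2 %/% 2) * pitch
  s <- sum(I)
  c(sum(rowSums(I) * x) / s, sum(colSums(I) * y) / s)
}

# erode a logical mask by k samples (box structuring element)
erode_mask <- function(M, k) {
  E <- M
  for (dx in -k:k) for (dy in -k:k) {
    S <- M
    if (dx > 0) S <- rbind(S[-(1:dx), , drop = FALSE],
                           matrix(FALSE, dx, ncol(S)))
    if (dx < 0) S <- rbind(matrix(FALSE, -dx, ncol(S)),
                           S[1:(nrow(S) + dx), , drop = FALSE])
    if (dy > 0) S <- cbind(S[, -(1:dy), drop = FALSE],
                           matrix(FALSE, nrow(S), dy))
    if (dy < 0) S <- cbind(matrix(FALSE, nrow(S), -dy),
                           S[, 1:(ncol(S) + dy), drop = FALSE])
    E <- E & S
  }
  E
}

# mean 10-90%-band widths (in samples) of rising and falling bar edges
# along x, averaged over rows
edge_widths <- function(img) {
  rises <- c(); falls <- c()
  n <- ncol(img)
  for (j in seq(50, n - 50, by = 10)) {
    v <- stats::filter(img[, j], rep(1 / 3, 3)); v[is.na(v)] <- 0
    thr_hi <- 0.9 * max(v); thr_lo <- 0.1 * max(v)
    if (max(v) < 0.2 * max(img)) next
    above <- v > 0.5 * max(v)
    for (k in which(diff(above) != 0)) {
      seg <- v[max(1, k - 15):min(nrow(img), k + 15)]
      w <- sum(seg > thr_lo & seg < thr_hi)
      if (diff(above)[k] > 0) rises <- c(rises, w) else falls <- c(falls, w)
    }
  }
  c(rise = mean(rises), fall = mean(falls))
}
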
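# Internal FFT helpers shared by the diffraction engine.
#
# Grid convention: an N-sample axis has its origin (optical axis) at the
# 0-based index N/2, i.e. R index N/2 + 1.  `fft_freqs` returns the matching
# frequency axis in cycles/mm in *natural fft order* (DC first), so transfer
# functions can be applied without shifting the spectrum.

fft_freqs <- function(n, pitch) {
  c(0:(n %/% 2 - 1L), -(n - n %/% 2):-1L) / (n * pitch)
}

# circularly shift a matrix so that the centre sample (N/2 + 1) moves to
# [1, 1]; for even dimensions this is its own inverse.
fft_shift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((n1 %/% 2 + 1L):n1, 1L:(n1 %/% 2))
  i2 <- c((n2 %/% 2 + 1L):n2, 1L:(n2 %/% 2))
  m[i1, i2, drop = FALSE]
}

fft2_centered <- function(m) fft_shift2(stats::fft(fft_shift2(m)))

ifft2_centered <- function(m) {
  fft_shift2(stats::fft(fft_shift2(m), inverse = TRUE)) / length(m)
}

# Scaled discrete Fourier transform (Bluestein / chirp-z), one axis:
#   B[v] = sum_u A[u] exp(-2i*pi*alpha*u*v),
# u = j1 - n/2 (j1 = 0..n-1), v = j2 - m/2 (j2 = 0..m-1).
# Unlike the plain FFT (alpha = 1/n) the frequency step alpha is arbitrary,
# which lets the focal-plane field be sampled at a chosen output pitch.
czt_axis <- function(A, alpha, m_out = nrow(A)) {
  n <- nrow(A)
  u <- (0:(n - 1L)) - n %/% 2L
  v <- (0:(m_out - 1L)) - m_out %/% 2L
  wmin <- min(v) - max(u)
  wmax <- max(v) - min(u)
  w <- wmin:wmax
  L <- stats::nextn(n + length(w) - 1L, 2)

  pre  <- exp(-1i * pi * alpha * u^2)  # applied to input samples
  post <- exp(-1i * pi * alpha * v^2)  # applied to output samples
  ker  <- exp(+1i * pi * alpha * w^2)  # convolution kernel

  a <- matrix(0i, L, ncol(A))
  a[seq_len(n), ] <- A * pre
  h <- complex(length.out = L)
  h[seq_along(w)] <- ker
  H <- stats::fft(h)
  conv <- stats::mvfft(stats::mvfft(a) * H, inverse = TRUE) / L
  # conv row r collects terms with u_index + w_index = r + 1, i.e.
  # u + w = (r - 1) - n%/%2 + wmin; select rows where u + w = v
  rows <- v + n %/% 2L - wmin + 1L
  conv[rows, , drop = FALSE] * post
}

# 2-D scaled DFT with common alpha on both axes (square pixels).
czt2 <- function(A, alpha, m_out = dim(A)) {
  if (length(m_out) == 1L) m_out <- c(m_out, m_out)
  B <- czt_axis(A, alpha, m_out[1L])
  t(czt_axis(t(B), alpha, m_out[2L]))
}
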
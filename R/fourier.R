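# Discrete Fourier conventions shared by the simulator, the sideband
# correction and the reconstruction. Storage follows the usual FFT layout
# (DC at index [1,1]); all geometric logic uses centred integer frequencies
# k in {-N/2, ..., N/2-1} with s = k / (N * pixel_size) in 1/Angstrom.
# Grids must have even side length.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

fft3 <- function(x) stats::fft(x)

ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# centred integer frequencies for an even-sized axis
freq_index <- function(n) {
  if (n %% 2 != 0) stop("grid side must be even")
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

# matrices of integer frequency components; kx varies along rows (dim 1)
freq_grid2 <- function(n) {
  k <- freq_index(n)
  list(kx = matrix(k, n, n), ky = matrix(k, n, n, byrow = TRUE))
}

# index permutation mapping k -> -k (self-inverse, pairs Friedel mates)
conj_index <- function(n) c(1L, n:2L)

# Hermitian residual relative to the largest coefficient
hermitian_residual <- function(ft) {
  ci <- conj_index(nrow(ft))
  m <- max(Mod(ft))
  if (m == 0) return(0)
  max(Mod(ft - Conj(ft[ci, ci]))) / m
}

stopifnot_hermitian <- function(ft, tol = 1e-8, what = "transform") {
  if (hermitian_residual(ft) > tol)
    stop(what, " is not Hermitian (did it come from a real image?)")
  invisible(TRUE)
}

# swap half-spaces so the centred element (n/2+1) moves to index 1 and back;
# for even n the shift is its own inverse
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# multiply a 2D transform by the phase ramp that moves the real-space origin
# to pixel `center` (1-based), so phases are referred to the particle centre
phase_center2 <- function(ft, center) {
  n <- nrow(ft)
  g <- freq_grid2(n)
  ft * exp(2i * pi * (g$kx * (center[1] - 1) + g$ky * (center[2] - 1)) / n)
}

# real part with a guard that the imaginary residual is negligible
take_real <- function(x, tol = 1e-6, what = "inverse transform") {
  rms <- sqrt(mean(Re(x)^2))
  if (rms > 0 && max(abs(Im(x))) / rms > tol)
    warning(what, " has non-negligible imaginary part (",
            format(max(abs(Im(x))) / rms), ")")
  Re(x)
}
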
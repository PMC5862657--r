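# Sideband overlap fraction A and the per-sample insertion weight
# W = 1 + A(2|sin chi| - 1), plus a Monte-Carlo disc-overlap oracle used to
# verify the closed form independently.

#' Fractional overlap of the two sideband discs
#'
#' The two sideband copies of a Fourier component at spacing `resolution`
#' are discs of diameter D whose centres are \eqn{2\Delta F\lambda/d} apart.
#' Their fractional common area, in terms of the reduced centre distance
#' \eqn{u = 2\Delta F\lambda/(dD)}, is
#' \deqn{A = \frac{2}{\pi}\left[\arccos u - u\sin(\arccos u)\right]}
#' for \eqn{u < 1} and 0 beyond (no overlap); at zero defocus A = 1. This is
#' the standard two-circle lens area normalised by the disc area, continuous
#' and strictly decreasing on `[0, 1]`.
#'
#' @param defocus defocus in Angstrom (>= 0).
#' @param particle_diameter D in Angstrom.
#' @param resolution spacing d in Angstrom.
#' @param wavelength electron wavelength in Angstrom.
#' @return overlap fraction in `[0, 1]`. Vectorised over all arguments.
#' @seealso [disc_overlap_oracle()] for an independent geometric check,
#'   [insertion_weight()] for its use.
#' @export
overlap_fraction <- function(defocus, particle_diameter, resolution,
                             wavelength) {
  .check_pos(particle_diameter = particle_diameter, resolution = resolution,
             wavelength = wavelength)
  if (any(defocus < 0)) stop("defocus must be >= 0")
  u <- 2 * defocus * wavelength / (resolution * particle_diameter)
  .lens_fraction(u)
}

# fractional common area of two unit-diameter discs at centre distance u
.lens_fraction <- function(u) {
  uc <- pmin(u, 1)
  out <- (2 / pi) * (acos(uc) - uc * sin(acos(uc)))
  out[u >= 1] <- 0
  out
}

#' Insertion weight for the 3D summation denominator
#'
#' \eqn{W = 1 + A(2|\sin\chi| - 1)}: where the sidebands do not overlap
#' (A = 0) every extracted component carries full weight 1; where they
#' overlap completely (A = 1) the weight equals the magnitude of the
#' conventional transfer \eqn{2|\sin\chi|}. W always lies between
#' \eqn{\min(1, 2|\sin\chi|)} and \eqn{\max(1, 2|\sin\chi|)}.
#'
#' @param chi_val aberration phase in radians (vectorised).
#' @param overlap overlap fraction A in `[0, 1]` (vectorised, recycled).
#' @return weight W.
#' @export
insertion_weight <- function(chi_val, overlap) {
  if (any(overlap < 0 | overlap > 1)) stop("overlap must lie in [0, 1]")
  1 + overlap * (2 * abs(sin(chi_val)) - 1)
}

#' Monte-Carlo disc-overlap oracle
#'
#' Estimates the fractional common area of two unit-diameter discs whose
#' centres are `u` diameters apart by sampling points uniformly in one disc
#' and counting the fraction that also fall in the other. Serves as an
#' independent geometric check of [overlap_fraction()].
#'
#' @param u centre distance in units of the disc diameter (>= 0).
#' @param n_samples number of points (>= 1e5 recommended for a useful
#'   standard error).
#' @param seed integer RNG seed.
#' @return list with `estimate`, `se` (binomial standard error) and `n`.
#' @export
disc_overlap_oracle <- function(u, n_samples = 1e6, seed = 1) {
  if (u < 0) stop("u must be >= 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  r <- 0.5 * sqrt(stats::runif(n_samples))
  a <- stats::runif(n_samples, 0, 2 * pi)
  x <- r * cos(a)
  y <- r * sin(a)
  inside <- (x - u)^2 + y^2 <= 0.25
  p <- mean(inside)
  list(estimate = p, se = sqrt(max(p * (1 - p), 1 / n_samples) / n_samples),
       n = n_samples)
}
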
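# Ewald-sphere geometry: sideband offsets and separations, minimum defocus,
# the particle-size significance threshold, and box-size requirements. All
# lengths in Angstrom, frequencies in 1/Angstrom; the small-angle
# approximation theta = lambda/d is used throughout.

.check_pos <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] <= 0))
      stop(nm, " must be positive and finite")
  invisible(TRUE)
}

#' Ewald-sphere deviation from the central section
#'
#' The offset \eqn{\Delta z^\ast = \lambda / 2 d^2} (in 1/Angstrom) of a
#' Fourier component at spacing `d` from the flat central section. The two
#' pseudo-Friedel-related components sit at \eqn{\pm\Delta z^\ast}, i.e.
#' \eqn{2\Delta z^\ast} apart along \eqn{z^\ast}: at 300 keV
#' (lambda = 0.02 A) and d = 3 A this is 1/900 per component and 1/450
#' between them.
#'
#' @param resolution spacing d in Angstrom.
#' @param wavelength electron wavelength in Angstrom.
#' @return offset in 1/Angstrom. Vectorised.
#' @export
delta_zstar <- function(resolution, wavelength) {
  .check_pos(resolution = resolution, wavelength = wavelength)
  wavelength / (2 * resolution^2)
}

#' In-image separation of the two sidebands
#'
#' Distance \eqn{2\Delta F \lambda / d} (Angstrom) between the centres of the
#' two displaced sideband copies of a Fourier component at spacing `d` in an
#' image at defocus `defocus`.
#'
#' @param defocus defocus in Angstrom (underfocus positive).
#' @param wavelength electron wavelength in Angstrom.
#' @param resolution spacing d in Angstrom.
#' @return separation in Angstrom. Vectorised; zero defocus gives zero.
#' @export
sideband_separation <- function(defocus, wavelength, resolution) {
  .check_pos(wavelength = wavelength, resolution = resolution)
  if (any(defocus < 0)) stop("defocus must be >= 0")
  2 * defocus * wavelength / resolution
}

#' Minimum defocus that fully separates the sidebands
#'
#' \eqn{Dd/2\lambda}: above this defocus the two sideband copies of every
#' Fourier component at spacing `resolution` or finer no longer overlap the
#' particle (separation exceeds the particle diameter). For a 100 A particle
#' at 4 A and lambda = 0.02 A this is 1 um; for a 1000 A particle, 10 um.
#'
#' @param particle_diameter D in Angstrom.
#' @param resolution spacing d in Angstrom.
#' @param wavelength electron wavelength in Angstrom.
#' @return defocus in Angstrom. Vectorised.
#' @export
min_defocus <- function(particle_diameter, resolution, wavelength) {
  .check_pos(particle_diameter = particle_diameter, resolution = resolution,
             wavelength = wavelength)
  particle_diameter * resolution / (2 * wavelength)
}

#' Particle diameter beyond which curvature correction matters
#'
#' The diameter at which the \eqn{z^\ast} separation of the two sidebands,
#' \eqn{2\Delta z^\ast = \lambda/d^2}, equals the transform's feature scale
#' 1/D: \eqn{D = d^2/\lambda}. Particles larger than this see a substantial
#' effect from Ewald-sphere curvature at spacings of `resolution` or finer
#' (450 A at 3 A and 300 keV; about half that at 100 keV).
#'
#' @inheritParams min_defocus
#' @return diameter in Angstrom. Vectorised.
#' @export
significance_diameter <- function(resolution, wavelength) {
  .check_pos(resolution = resolution, wavelength = wavelength)
  resolution^2 / wavelength
}

#' Minimum box edge containing particle plus delocalised sidebands
#'
#' \eqn{D + 2\Delta F\lambda/d}: the boxed area must hold the particle and
#' both sideband copies of the finest spacing of interest, otherwise the
#' delocalised fringes wrap or are lost.
#'
#' @inheritParams min_defocus
#' @param defocus defocus in Angstrom.
#' @return box edge in Angstrom. Vectorised.
#' @export
required_box_size <- function(particle_diameter, defocus, wavelength,
                              resolution) {
  .check_pos(particle_diameter = particle_diameter, wavelength = wavelength,
             resolution = resolution)
  particle_diameter + sideband_separation(defocus, wavelength, resolution)
}

#' Tabulate the defocus needed for full sideband separation
#'
#' Evaluates [min_defocus()] over the cross product of electron energies,
#' particle diameters and resolutions, for regenerating separation-threshold
#' curves (defocus versus energy at fixed D, or versus D at fixed energy).
#'
#' @param energies_kev electron energies in keV (non-empty).
#' @param diameters_a particle diameters in Angstrom (non-empty).
#' @param resolutions_a spacings in Angstrom (non-empty).
#' @param rounded_wavelength use wavelengths rounded to two significant
#'   figures (0.02 A at 300 keV, 0.037 A at 100 keV) instead of the full
#'   relativistic values, so that textbook numbers are reproduced exactly.
#' @return a data.frame with columns `voltage_kev`, `wavelength`,
#'   `diameter`, `resolution`, `min_defocus` (A) and `min_defocus_um`.
#' @export
geometry_table <- function(energies_kev, diameters_a, resolutions_a,
                           rounded_wavelength = FALSE) {
  if (length(energies_kev) == 0 || length(diameters_a) == 0 ||
      length(resolutions_a) == 0)
    stop("energies_kev, diameters_a and resolutions_a must be non-empty")
  tab <- expand.grid(voltage_kev = energies_kev, diameter = diameters_a,
                     resolution = resolutions_a, KEEP.OUT.ATTRS = FALSE)
  lam <- electron_wavelength(tab$voltage_kev)
  if (rounded_wavelength) lam <- signif(lam, 2)
  tab$wavelength <- lam
  tab$min_defocus <- min_defocus(tab$diameter, tab$resolution, lam)
  tab$min_defocus_um <- tab$min_defocus / 1e4
  tab[, c("voltage_kev", "wavelength", "diameter", "resolution",
          "min_defocus", "min_defocus_um")]
}
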
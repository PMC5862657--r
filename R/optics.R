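# Scalar contrast-transfer optics: electron wavelength, the aberration phase
# chi, and the real (CTFR) and complex single-sideband (CTFP/CTFQ) transfer
# functions.

# CODATA 2018 constants (SI)
.planck <- 6.62607015e-34
.m0 <- 9.1093837015e-31
.echarge <- 1.602176634e-19
.clight <- 299792458

#' Relativistic electron wavelength
#'
#' Wavelength of an electron accelerated through `voltage_kev` kilovolts,
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}}, in Angstrom.
#' At 300 keV this gives 0.0197 A (commonly quoted rounded to 0.02 A) and at
#' 100 keV 0.037 A.
#'
#' @param voltage_kev accelerating voltage in keV; must be positive.
#' @return wavelength in Angstrom.
#' @export
#' @examples
#' electron_wavelength(300)  # ~0.0197 A
electron_wavelength <- function(voltage_kev) {
  if (any(!is.finite(voltage_kev)) || any(voltage_kev <= 0))
    stop("voltage_kev must be positive and finite")
  v <- voltage_kev * 1e3
  .planck / sqrt(2 * .m0 * .echarge * v *
                   (1 + .echarge * v / (2 * .m0 * .clight^2))) * 1e10
}

#' Optical model for a defocused bright-field image
#'
#' Bundles everything the aberration phase needs: wavelength (or voltage),
#' defocus, spherical aberration, amplitude contrast, an optional constant
#' extra phase (phase plate), and two-fold astigmatism.
#'
#' Sign convention: positive `defocus` means underfocus (objective focused
#' below the specimen), which makes the aberration phase negative at low
#' resolution so that the conventional transfer \eqn{-2\sin\chi} gives
#' positive low-resolution contrast. Display conventions that print
#' underfocus with a minus sign (e.g. "-1.1 um") refer to the same physical
#' state.
#'
#' @param voltage_kev accelerating voltage in keV. May be omitted when
#'   `wavelength` is given.
#' @param defocus defocus \eqn{\Delta F} in Angstrom, positive = underfocus.
#' @param cs third-order spherical aberration coefficient in Angstrom
#'   (1 mm = 1e7 A).
#' @param amp_contrast amplitude-contrast fraction in `[0, 1)`. Default:
#'   0.04 for >= 200 keV, 0.07 below (the customary values at 300 and
#'   100 keV). Pass 0 explicitly for a pure weak-phase model.
#' @param extra_phase constant additional phase in radians (models a Zernike
#'   phase plate), default 0.
#' @param astig_amount defocus difference (max minus min) in Angstrom.
#' @param astig_angle azimuth of the astigmatism axis in radians.
#' @param wavelength electron wavelength in Angstrom. Computed from
#'   `voltage_kev` when omitted; when both are given they must agree within
#'   1%. Supplying `wavelength` alone is allowed (useful for rounded or
#'   grid-scaled values).
#' @return an object of class `optical_model`.
#' @export
optical_model <- function(voltage_kev = NULL, defocus = 0, cs = 0,
                          amp_contrast = NULL, extra_phase = 0,
                          astig_amount = 0, astig_angle = 0,
                          wavelength = NULL) {
  if (is.null(voltage_kev) && is.null(wavelength))
    stop("supply voltage_kev or wavelength")
  if (is.null(wavelength)) {
    wavelength <- electron_wavelength(voltage_kev)
  } else {
    if (wavelength <= 0) stop("wavelength must be positive")
    if (!is.null(voltage_kev)) {
      lam_v <- electron_wavelength(voltage_kev)
      if (abs(wavelength - lam_v) / lam_v > 0.01)
        stop(sprintf(
          "wavelength %.4g A inconsistent (>1%%) with voltage %.4g keV (%.4g A)",
          wavelength, voltage_kev, lam_v))
    }
  }
  if (is.null(amp_contrast))
    amp_contrast <- if (!is.null(voltage_kev) && voltage_kev < 200) 0.07 else 0.04
  if (amp_contrast < 0 || amp_contrast >= 1)
    stop("amp_contrast must be in [0, 1)")
  structure(list(voltage_kev = voltage_kev, wavelength = wavelength,
                 defocus = defocus, cs = cs, amp_contrast = amp_contrast,
                 extra_phase = extra_phase, astig_amount = astig_amount,
                 astig_angle = astig_angle),
            class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat(sprintf(
    "optical_model: lambda %.4g A, defocus %.6g A, Cs %.4g A, W_amp %.3g\n",
    x$wavelength, x$defocus, x$cs, x$amp_contrast))
  if (x$astig_amount != 0)
    cat(sprintf("  astigmatism %.4g A at %.3g rad\n",
                x$astig_amount, x$astig_angle))
  if (x$extra_phase != 0)
    cat(sprintf("  extra phase %.4g rad\n", x$extra_phase))
  invisible(x)
}

#' Aberration phase of the objective lens
#'
#' \eqn{\chi(s) = -\frac{2\pi}{\lambda}\left(\frac{\Delta F\,\theta^2}{2} -
#' \frac{C_s\,\theta^4}{4}\right)} with the small diffraction angle
#' \eqn{\theta = \lambda s}. With two-fold astigmatism the defocus is
#' replaced by the azimuth-dependent effective defocus
#' \eqn{\Delta F + (a/2)\cos 2(\phi - \phi_a)}; the model's constant
#' `extra_phase` is added.
#'
#' @param spatial_freq spatial frequency magnitude in 1/Angstrom (>= 0);
#'   vectorised.
#' @param model an [optical_model].
#' @param azimuth frequency azimuth in radians (only matters with
#'   astigmatism); recycled against `spatial_freq`.
#' @return phase in radians.
#' @export
chi <- function(spatial_freq, model, azimuth = 0) {
  if (any(spatial_freq < 0)) stop("spatial_freq must be >= 0")
  lam <- model$wavelength
  df <- model$defocus
  if (model$astig_amount != 0)
    df <- df + (model$astig_amount / 2) * cos(2 * (azimuth - model$astig_angle))
  theta2 <- (lam * spatial_freq)^2
  -2 * pi / lam * (df * theta2 / 2 - model$cs * theta2^2 / 4) +
    model$extra_phase
}

# phase angle of the amplitude-contrast admixture
.amp_delta <- function(model) asin(model$amp_contrast)

#' Single-sideband and conventional contrast transfer functions
#'
#' `ctf_p` and `ctf_q` are the two complex single-sideband transfer values
#' \eqn{e^{\pm i(\chi + \pi/2 - \delta)}} with \eqn{\delta = \arcsin
#' W_{amp}}; they have unit modulus (they alter phases only) and are complex
#' conjugates of one another. Their sum is the conventional real transfer
#' `ctf_r`, which equals \eqn{-2\sin\chi} for a pure phase object and
#' \eqn{2(W\cos\chi - \sqrt{1-W^2}\sin\chi)} with amplitude contrast; the
#' identity `ctf_p + ctf_q == ctf_r` holds to machine precision.
#'
#' The amplitude-contrast shift enters the exponent with the sign that makes
#' the explicit \eqn{W\cos\chi} form exact under this package's defocus
#' convention (underfocus positive, \eqn{\chi < 0} at low resolution, so
#' amplitude contrast adds to the low-resolution contrast). The magnitude of
#' the total scattering phase offset, \eqn{\pi/2 + \arcsin W}, is reported
#' by [amp_phase_offset()] (about 94 degrees for W = 0.07).
#'
#' @param chi_val aberration phase in radians (vectorised).
#' @param model an [optical_model] (only `amp_contrast` is used here).
#' @return complex (`ctf_p`, `ctf_q`) or real (`ctf_r`) transfer values.
#' @export
ctf_p <- function(chi_val, model) {
  exp(1i * (chi_val + pi / 2 - .amp_delta(model)))
}

#' @rdname ctf_p
#' @export
ctf_q <- function(chi_val, model) {
  exp(-1i * (chi_val + pi / 2 - .amp_delta(model)))
}

#' @rdname ctf_p
#' @export
ctf_r <- function(chi_val, model) {
  w <- model$amp_contrast
  2 * (w * cos(chi_val) - sqrt(1 - w^2) * sin(chi_val))
}

#' Scattering phase offset with amplitude contrast
#'
#' Magnitude of the constant phase offset applied inside the single-sideband
#' exponents: \eqn{\pi/2 + \arcsin W_{amp}}, i.e. the 90-degree phase shift
#' upon scattering enlarged by the amplitude-contrast admixture. For
#' W = 0.07 this is 94.0 degrees.
#'
#' @param amp_contrast amplitude-contrast fraction in `[0, 1)`.
#' @param unit `"deg"` (default) or `"rad"`.
#' @return the offset magnitude.
#' @export
amp_phase_offset <- function(amp_contrast, unit = c("deg", "rad")) {
  unit <- match.arg(unit)
  if (any(amp_contrast < 0 | amp_contrast >= 1))
    stop("amp_contrast must be in [0, 1)")
  off <- pi / 2 + asin(amp_contrast)
  if (unit == "deg") off * 180 / pi else off
}
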
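# The single-sideband correction itself: Friedel-consistent half-plane
# application of the complex transfer functions, the rotated multi-sector
# procedure, soft masking, and extraction of per-frequency AMP/PHS/ZSTAR
# sideband samples.

#' Sector plan for the multi-pass correction
#'
#' The half-plane split has a discontinuity along its boundary axis, so the
#' correction is run in several passes with rotated boundaries and, for each
#' frequency, the pass whose boundary lies angularly farthest is kept. With
#' `n_sectors` sectors there are `n_sectors/2` passes with boundary axes at
#' multiples of `pi/(n_sectors/2)`; every frequency is then at least
#' `pi/n_sectors` away from the boundary of its selected pass. The default
#' 8-sector plan uses 4 passes at 0, 45, 90 and 135 degrees.
#'
#' @param n_sectors even sector count: 2, 4, 6 or 8.
#' @param angles optional explicit boundary-axis angles in radians
#'   (overrides `n_sectors`); a single rotated sector is `angles = a`.
#' @return an object of class `sector_plan`.
#' @export
sector_plan <- function(n_sectors = 8, angles = NULL) {
  if (is.null(angles)) {
    if (!n_sectors %in% c(2, 4, 6, 8))
      stop("n_sectors must be one of 2, 4, 6, 8")
    n_pass <- n_sectors / 2
    angles <- (seq_len(n_pass) - 1) * pi / n_pass
  }
  structure(list(angles = angles, n_sectors = 2 * length(angles),
                 keep_margin = pi / (2 * length(angles))),
            class = "sector_plan")
}

# signed half-plane assignment for every storage frequency: +1 on the
# positive side of the boundary axis at `angle`, -1 on the other, ties on
# the axis broken by the along-axis coordinate (+x-like ray -> +1), 0 at
# DC. The -n/2 Nyquist coordinate is its own negative in storage (the mate
# of (kx, -n/2) is (-kx, -n/2)), so it is folded to 0 before the sign is
# computed; this keeps the assignment odd under the storage Friedel map on
# the Nyquist row/column, and 0 exactly on the self-conjugate frequencies.
half_plane_sign <- function(n, angle) {
  g <- freq_grid2(n)
  kx <- ifelse(g$kx == -n / 2, 0, g$kx)
  ky <- ifelse(g$ky == -n / 2, 0, g$ky)
  cross <- -kx * sin(angle) + ky * cos(angle)
  along <- kx * cos(angle) + ky * sin(angle)
  tol <- 1e-6
  sgn <- sign(cross)
  on_axis <- abs(cross) < tol
  sgn[on_axis] <- sign(along[on_axis])
  sgn
}

# frequencies whose Friedel mate is themselves in storage (DC and the
# -N/2 Nyquist row/column); complex factors must not touch these
self_conjugate_mask <- function(n) {
  g <- freq_grid2(n)
  (g$kx == 0 | g$kx == -n / 2) & (g$ky == 0 | g$ky == -n / 2)
}

.chi_grid <- function(n, pixel_size, model) {
  g <- freq_grid2(n)
  s <- sqrt(g$kx^2 + g$ky^2) / (n * pixel_size)
  az <- atan2(g$ky, g$kx)
  chi(s, model, az)
}

#' Apply a single-sideband complex CTF correction to a transform
#'
#' Multiplies one half of a Hermitian 2D transform by CTFP and the other by
#' CTFQ (swapped for `side = "Q"`), which retains the Friedel relationship
#' so the corrected image stays real. Frequencies exactly on the boundary
#' axis follow the positive ray with the P-multiplied half and the negative
#' ray with the Q-multiplied half. The zero frequency is left untouched (the
#' mean carries no phase-contrast information and a complex factor would
#' make it imaginary), as are the self-conjugate Nyquist edge frequencies,
#' which have no separate Friedel partner in an even-sized storage grid.
#'
#' Applying side P and then side Q with the same boundary restores the
#' original transform exactly (CTFP * CTFQ = 1), and the sum of the P- and
#' Q-corrected transforms equals the CTFR-corrected transform on every
#' frequency the complex factors touch.
#'
#' @param ft complex N x N transform of a real image (Hermitian; checked).
#' @param model an [optical_model].
#' @param pixel_size pixel size in Angstrom.
#' @param boundary_angle boundary-axis angle in radians (default 0: the
#'   boundary is the x-axis, the halves are the upper/lower half-planes).
#' @param side `"P"` or `"Q"`: which sideband the correction targets.
#' @param check check Hermitian symmetry of the input (set `FALSE` to skip
#'   when the caller guarantees it).
#' @return the corrected transform (same shape, still Hermitian).
#' @export
apply_complex_ctf <- function(ft, model, pixel_size, boundary_angle = 0,
                              side = c("P", "Q"), check = TRUE) {
  side <- match.arg(side)
  n <- nrow(ft)
  if (ncol(ft) != n) stop("transform must be square")
  if (check) stopifnot_hermitian(ft, 1e-8, "input transform")
  chiv <- .chi_grid(n, pixel_size, model)
  sgn <- half_plane_sign(n, boundary_angle)
  if (side == "Q") sgn <- -sgn
  fac <- matrix(complex(real = 1, imaginary = 0), n, n)
  fac[sgn > 0] <- ctf_p(chiv[sgn > 0], model)
  fac[sgn < 0] <- ctf_q(chiv[sgn < 0], model)
  fac[self_conjugate_mask(n)] <- 1
  ft * fac
}

#' Apply the conventional real CTF to a transform
#'
#' Multiplies a 2D transform by the real transfer function. With
#' `normalization = "sum"` the factor is \eqn{CTFR = -2\sin\chi} (the sum
#' CTFP + CTFQ), which makes `apply_ctfr` the exact pointwise sum of the two
#' single-sideband corrections away from the untouched DC/Nyquist
#' frequencies. With `"half"` the factor is \eqn{CTFR/2 = -\sin\chi}, the
#' unit-peak convention most CTF-correction software uses; under it a fully
#' delocalised fringe keeps its original amplitude on the particle and
#' leaves ghosts of half that amplitude at twice the displacement.
#'
#' @inheritParams apply_complex_ctf
#' @param normalization `"sum"` or `"half"`.
#' @return the corrected transform.
#' @export
apply_ctfr <- function(ft, model, pixel_size,
                       normalization = c("sum", "half"), check = TRUE) {
  normalization <- match.arg(normalization)
  n <- nrow(ft)
  if (check) stopifnot_hermitian(ft, 1e-8, "input transform")
  fac <- ctf_r(.chi_grid(n, pixel_size, model), model)
  if (normalization == "half") fac <- fac / 2
  ft * fac
}

#' Soft circular mask
#'
#' Multiplies an image by a radial raised-cosine window: 1 inside
#' `diameter/2`, a smooth half-cosine descent to 0 over `edge_width`, 0
#' beyond. `edge_width = 0` gives a hard disc. The window is idempotent on
#' its plateau and isotropic, which avoids imprinting a preferred direction
#' on the extracted Fourier components.
#'
#' @param image real N x N matrix.
#' @param pixel_size pixel size in Angstrom.
#' @param diameter plateau diameter in Angstrom.
#' @param edge_width raised-cosine edge width in Angstrom.
#' @param center mask centre in pixels (1-based), default the grid centre
#'   `(N/2+1, N/2+1)`.
#' @return the masked image.
#' @export
soft_mask <- function(image, pixel_size, diameter, edge_width = 0,
                      center = NULL) {
  n <- nrow(image)
  if (is.null(center)) center <- c(n / 2 + 1, n / 2 + 1)
  if (diameter <= 0 || edge_width < 0) stop("bad mask dimensions")
  if (diameter + 2 * edge_width > n * pixel_size)
    stop("mask (diameter + 2*edge_width) exceeds the image")
  image * soft_mask_window(n, pixel_size, diameter, edge_width, center)
}

soft_mask_window <- function(n, pixel_size, diameter, edge_width, center) {
  x <- (seq_len(n) - center[1]) * pixel_size
  y <- (seq_len(n) - center[2]) * pixel_size
  r <- sqrt(outer(x^2, y^2, `+`))
  r0 <- diameter / 2
  w <- matrix(0, n, n)
  w[r <= r0] <- 1
  if (edge_width > 0) {
    band <- r > r0 & r < r0 + edge_width
    w[band] <- 0.5 * (1 + cos(pi * (r[band] - r0) / edge_width))
  }
  w
}

# pass index (into plan$angles) maximising the angular distance between each
# frequency's azimuth and the pass's boundary line (distance taken mod pi)
pass_selection <- function(n, plan) {
  g <- freq_grid2(n)
  phi <- atan2(g$ky, g$kx)
  best <- matrix(1L, n, n)
  bestd <- matrix(-1, n, n)
  for (m in seq_along(plan$angles)) {
    d <- abs(((phi - plan$angles[m] + pi / 2) %% pi) - pi / 2)
    d <- pmin(d, pi - d)
    upd <- d > bestd
    best[upd] <- m
    bestd[upd] <- d[upd]
  }
  best
}

#' Single-sideband correction and sideband-sample extraction
#'
#' Runs the full per-particle correction: for every pass of the sector plan
#' and each side P and Q, the image transform is multiplied half-plane-wise
#' by CTFP/CTFQ, inverse transformed, soft-masked around the particle to
#' discard the doubly-delocalised wrong-sideband ghost, and transformed
#' again. The final per-frequency samples are assembled by taking, for every
#' frequency, the pass whose boundary axis is angularly farthest, which
#' removes the boundary discontinuity of a single split.
#'
#' Each returned side carries per-frequency amplitude, phase and a signed
#' \eqn{z^\ast} offset \eqn{\pm\lambda|s|^2/2}: the P side samples the 3D
#' transform at \eqn{+\Delta z^\ast} on the positive side of its boundary
#' (its Friedel mates at \eqn{-\Delta z^\ast} on the other), the Q side the
#' reverse. The curvature direction convention (+z toward the electron
#' source) matches [forward_image()]; self-consistency of the two is
#' enforced by the package tests.
#'
#' @param image real square image (the boxed particle, centred).
#' @param model an [optical_model] carrying the particle's defocus.
#' @param pixel_size pixel size in Angstrom.
#' @param particle_diameter particle diameter D in Angstrom (sets mask
#'   defaults and the separation warning).
#' @param plan a [sector_plan]; default 8 sectors.
#' @param mask_diameter soft-mask plateau diameter in Angstrom, default
#'   `1.2 * particle_diameter`.
#' @param mask_edge raised-cosine edge width in Angstrom, default
#'   `0.1 * particle_diameter`.
#' @param center particle centre in pixels, default the grid centre.
#' @param warn_overlap warn when the defocus is below the full-separation
#'   threshold at Nyquist (the overlapped shells cannot be cleanly
#'   separated; their overlap fraction is attached to the warning).
#' @return an object of class `sideband_samples` - a list with elements `P`
#'   and `Q`, each holding `values` (complex N x N), `amp`, `phs`, `zstar`
#'   (signed, 1/Angstrom) and `side`, plus `pixel_size`, `plan` and the mask
#'   parameters.
#' @export
sideband_correct <- function(image, model, pixel_size, particle_diameter,
                             plan = sector_plan(8), mask_diameter = NULL,
                             mask_edge = NULL, center = NULL,
                             warn_overlap = TRUE) {
  n <- nrow(image)
  if (ncol(image) != n) stop("image must be square")
  if (is.null(mask_diameter)) mask_diameter <- 1.2 * particle_diameter
  if (is.null(mask_edge)) mask_edge <- 0.1 * particle_diameter
  if (is.null(center)) center <- c(n / 2 + 1, n / 2 + 1)

  d_nyq <- 2 * pixel_size
  if (warn_overlap) {
    thr <- min_defocus(particle_diameter, d_nyq, model$wavelength)
    if (model$defocus < thr) {
      a_nyq <- overlap_fraction(model$defocus, particle_diameter, d_nyq,
                                model$wavelength)
      warning(sprintf(paste0(
        "defocus %.5g A is below the full-separation threshold %.5g A at ",
        "Nyquist; overlap fraction at Nyquist is %.3f"),
        model$defocus, thr, a_nyq))
    }
  }

  ft <- fft2(image)
  n_pass <- length(plan$angles)
  g_p <- array(0i, c(n, n, n_pass))
  g_q <- array(0i, c(n, n, n_pass))
  for (m in seq_len(n_pass)) {
    for (side in c("P", "Q")) {
      ftc <- apply_complex_ctf(ft, model, pixel_size,
                               boundary_angle = plan$angles[m],
                               side = side, check = (m == 1 && side == "P"))
      img <- take_real(ifft2(ftc), tol = 1e-6, what = "corrected image")
      msk <- soft_mask(img, pixel_size, mask_diameter, mask_edge, center)
      if (side == "P") g_p[, , m] <- fft2(msk) else g_q[, , m] <- fft2(msk)
    }
  }

  sel <- pass_selection(n, plan)
  lin <- seq_len(n * n) + (as.vector(sel) - 1L) * n * n
  vals_p <- matrix(g_p[lin], n, n)
  vals_q <- matrix(g_q[lin], n, n)

  # signed half-plane assignment of each frequency in its selected pass
  sgn <- matrix(0, n, n)
  for (m in seq_len(n_pass)) {
    hm <- half_plane_sign(n, plan$angles[m])
    use <- sel == m
    sgn[use] <- hm[use]
  }

  g <- freq_grid2(n)
  smag <- sqrt(g$kx^2 + g$ky^2) / (n * pixel_size)
  dz <- model$wavelength * smag^2 / 2

  mk_side <- function(values, side, zsign) {
    list(values = values, amp = Mod(values), phs = Arg(values),
         zstar = zsign * sgn * dz, side = side)
  }
  structure(list(P = mk_side(vals_p, "P", +1),
                 Q = mk_side(vals_q, "Q", -1),
                 pixel_size = pixel_size, plan = plan, center = center,
                 mask_diameter = mask_diameter, mask_edge = mask_edge,
                 particle_diameter = particle_diameter),
            class = "sideband_samples")
}

#' Band-limited fringe power envelope
#'
#' Smooth spatial envelope of the fringe power near one resolution band:
#' the transform is restricted to an annulus `|s|` within
#' `resolution^-1 * (1 +/- bandwidth)` (optionally to the half-plane of a
#' given azimuth, which yields the analytic-signal envelope) and the
#' squared modulus of the inverse transform is returned.
#'
#' @param image real square image.
#' @param pixel_size pixel size in Angstrom.
#' @param resolution band centre spacing d in Angstrom.
#' @param bandwidth fractional half-width of the annulus (default 0.2).
#' @param azimuth optional azimuth (radians); when given only frequencies
#'   within 90 degrees of it are kept.
#' @return real N x N envelope (arbitrary units).
#' @export
fringe_envelope <- function(image, pixel_size, resolution, bandwidth = 0.2,
                            azimuth = NULL) {
  n <- nrow(image)
  g <- freq_grid2(n)
  smag <- sqrt(g$kx^2 + g$ky^2) / (n * pixel_size)
  s0 <- 1 / resolution
  keep <- smag >= s0 * (1 - bandwidth) & smag <= s0 * (1 + bandwidth)
  if (!is.null(azimuth)) {
    keep <- keep & (g$kx * cos(azimuth) + g$ky * sin(azimuth)) > 0
  }
  ft <- fft2(image)
  ft[!keep] <- 0
  Mod(ifft2(ft))^2
}

#' Centroid of the strongest fringe patch
#'
#' Locates the global maximum of the fringe power envelope, then returns the
#' power-weighted centroid within `window_radius` of it, in Angstrom
#' relative to `center`. Used to measure where the fringes of one Fourier
#' component sit: before correction a sideband patch lies about
#' \eqn{\Delta F \lambda / d} from the particle centre, after a correct
#' single-sideband correction it returns onto the centre, and after a
#' wrong-side correction it lands at about twice the original displacement.
#'
#' @inheritParams fringe_envelope
#' @param center particle centre in pixels, default the grid centre.
#' @param window_radius optional centroid window radius in Angstrom around
#'   the envelope maximum; `NULL` (default) uses the whole envelope, which
#'   is the right choice for flat-topped patches. To isolate one of
#'   several patches, keep the radius comparable to the particle diameter.
#' @return list with `centroid` (length-2, Angstrom relative to `center`),
#'   `displacement` (its norm) and `peak` (the window centre used).
#' @export
fringe_power_centroid <- function(image, pixel_size, resolution,
                                  bandwidth = 0.2, azimuth = NULL,
                                  center = NULL, window_radius = NULL) {
  n <- nrow(image)
  if (is.null(center)) center <- c(n / 2 + 1, n / 2 + 1)
  env <- fringe_envelope(image, pixel_size, resolution, bandwidth, azimuth)
  if (max(env) <= 0 || sum(env) == 0)
    stop("no power in the requested frequency band")
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  x <- (seq_len(n) - center[1]) * pixel_size
  y <- (seq_len(n) - center[2]) * pixel_size
  xm <- matrix(x, n, n)
  ym <- matrix(y, n, n, byrow = TRUE)
  pkx <- x[pk[1]]
  pky <- y[pk[2]]
  w <- env
  if (!is.null(window_radius))
    w[(xm - pkx)^2 + (ym - pky)^2 > window_radius^2] <- 0
  tot <- sum(w)
  cen <- c(sum(w * xm), sum(w * ym)) / tot
  list(centroid = cen, displacement = sqrt(sum(cen^2)), peak = c(pkx, pky))
}

#' Fringe relocalisation distance between two images
#'
#' Distance in Angstrom between the windowed fringe-power centroids of two
#' images of the same particle (typically before and after a correction) at
#' the same test frequency.
#'
#' @param image_before,image_after real square images on the same grid.
#' @inheritParams fringe_power_centroid
#' @return distance in Angstrom.
#' @export
relocalization_distance <- function(image_before, image_after, pixel_size,
                                    resolution, bandwidth = 0.2,
                                    azimuth = NULL, center = NULL,
                                    window_radius = NULL) {
  cb <- fringe_power_centroid(image_before, pixel_size, resolution,
                              bandwidth, azimuth, center, window_radius)
  ca <- fringe_power_centroid(image_after, pixel_size, resolution,
                              bandwidth, azimuth, center, window_radius)
  sqrt(sum((cb$centroid - ca$centroid)^2))
}

#' Windowed RMS amplitude
#'
#' Root-mean-square of an image inside a disc window, the measurement used
#' to compare raw sideband, relocalised and ghost fringe strengths.
#'
#' @param image real square image.
#' @param pixel_size pixel size in Angstrom.
#' @param at window centre as an (x, y) offset in Angstrom from `center`.
#' @param radius window radius in Angstrom.
#' @param center reference centre in pixels, default the grid centre.
#' @return the RMS value.
#' @export
windowed_rms <- function(image, pixel_size, at, radius, center = NULL) {
  n <- nrow(image)
  if (is.null(center)) center <- c(n / 2 + 1, n / 2 + 1)
  x <- (seq_len(n) - center[1]) * pixel_size - at[1]
  y <- (seq_len(n) - center[2]) * pixel_size - at[2]
  inside <- outer(x^2, y^2, `+`) <= radius^2
  if (!any(inside)) stop("window lies outside the image")
  sqrt(mean(image[inside]^2))
}
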